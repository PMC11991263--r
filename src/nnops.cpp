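// Low-level kernels for the 1-D network engine: im2col convolution
// (forward + backward) and max-pooling. Activations travel as cubes of
// shape (channels, length, batch); convolution weights are stored as a
// (C_out x C_in*k) matrix whose column block kk holds the weights for
// kernel tap kk (tap-major, channel-minor).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col1d(const mat& x, int k, int stride, int pad, int Lout) {
  const int Cin = x.n_rows, L = x.n_cols;
  mat P(Cin * k, Lout, fill::zeros);
  for (int t = 0; t < Lout; ++t) {
    const int start = t * stride - pad;
    for (int kk = 0; kk < k; ++kk) {
      const int idx = start + kk;
      if (idx >= 0 && idx < L)
        P.submat(kk * Cin, t, (kk + 1) * Cin - 1, t) = x.col(idx);
    }
  }
  return P;
}

// im2col over the whole batch: (Cin*k) x (Lout*B), so the convolution is
// a single GEMM instead of one per batch slice.
static mat im2col1d_batch(const cube& x, int k, int stride, int pad,
                          int Lout) {
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  mat P(Cin * k, (size_t)Lout * B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& xs = x.slice(s);
    for (int t = 0; t < Lout; ++t) {
      const int start = t * stride - pad;
      const size_t col = (size_t)s * Lout + t;
      for (int kk = 0; kk < k; ++kk) {
        const int idx = start + kk;
        if (idx >= 0 && idx < L)
          P.submat(kk * Cin, col, (kk + 1) * Cin - 1, col) = xs.col(idx);
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k, int stride, int pad) {
  const int B = x.n_slices, L = x.n_cols;
  const int Lout = (L + 2 * pad - k) / stride + 1;
  const int Cout = W.n_rows;
  mat P = im2col1d_batch(x, k, stride, pad, Lout);
  mat Y = W * P;
  Y.each_col() += b;
  cube y(Cout, Lout, B);
  for (int s = 0; s < B; ++s)
    y.slice(s) = Y.cols((size_t)s * Lout, (size_t)(s + 1) * Lout - 1);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& gy, int k, int stride, int pad) {
  const int B = x.n_slices, L = x.n_cols;
  const int Cin = x.n_rows;
  const int Lout = gy.n_cols;
  mat P = im2col1d_batch(x, k, stride, pad, Lout);
  mat GY(gy.n_rows, (size_t)Lout * B);
  for (int s = 0; s < B; ++s)
    GY.cols((size_t)s * Lout, (size_t)(s + 1) * Lout - 1) = gy.slice(s);
  mat gW = GY * P.t();
  vec gb = sum(GY, 1);
  mat gP = W.t() * GY;
  cube gx(Cin, L, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    mat& gxs = gx.slice(s);
    for (int t = 0; t < Lout; ++t) {
      const int start = t * stride - pad;
      const size_t col = (size_t)s * Lout + t;
      for (int kk = 0; kk < k; ++kk) {
        const int idx = start + kk;
        if (idx >= 0 && idx < L)
          gxs.col(idx) += gP.submat(kk * Cin, col, (kk + 1) * Cin - 1, col);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// ---- fused residual block -------------------------------------------
// conv -> batch-norm -> SE -> ReLU -> conv -> batch-norm -> SE, plus an
// identity or 1x1-conv shortcut, then (out = ReLU(presum)). Keeping the
// whole chain in compiled code avoids the allocation churn of running
// the elementwise steps through the interpreter. The returned caches are
// exactly what the backward pass needs.

struct BnCache { mat xhat; vec istd; vec mu; vec var; bool batch; };

static cube bn_fwd(const cube& x, const vec& gamma, const vec& beta,
                   const vec& rm, const vec& rv, double eps, bool training,
                   BnCache& cc) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const double n = (double)L * B;
  mat xm(C, L * B);
  for (int s = 0; s < B; ++s) xm.cols(s * L, (s + 1) * L - 1) = x.slice(s);
  vec mu, v;
  if (training && n > 1) {
    mu = mean(xm, 1);
    xm.each_col() -= mu;
    v = sum(square(xm), 1) / n;
  } else {
    mu = rm; v = rv;
    xm.each_col() -= mu;
  }
  vec istd = 1.0 / sqrt(v + eps);
  xm.each_col() %= istd;              // xhat
  cc.xhat = xm; cc.istd = istd; cc.mu = mu; cc.var = v;
  cc.batch = training && n > 1;
  mat ym = xm;
  ym.each_col() %= gamma;
  ym.each_col() += beta;
  cube y(C, L, B);
  for (int s = 0; s < B; ++s) y.slice(s) = ym.cols(s * L, (s + 1) * L - 1);
  return y;
}

static cube bn_bwd(const cube& gy, const BnCache& cc, const vec& gamma,
                   vec& ggamma, vec& gbeta) {
  const int C = gy.n_rows, L = gy.n_cols, B = gy.n_slices;
  mat gym(C, L * B);
  for (int s = 0; s < B; ++s) gym.cols(s * L, (s + 1) * L - 1) = gy.slice(s);
  gbeta += sum(gym, 1);
  ggamma += sum(gym % cc.xhat, 1);
  mat gxhat = gym;
  gxhat.each_col() %= gamma;
  mat gxm;
  if (cc.batch) {
    vec m1 = mean(gxhat, 1);
    vec m2 = mean(gxhat % cc.xhat, 1);
    gxm = gxhat;
    gxm.each_col() -= m1;
    gxm -= cc.xhat.each_col() % m2;
    gxm.each_col() %= cc.istd;
  } else {
    gxm = gxhat;
    gxm.each_col() %= cc.istd;
  }
  cube gx(C, L, B);
  for (int s = 0; s < B; ++s) gx.slice(s) = gxm.cols(s * L, (s + 1) * L - 1);
  return gx;
}

struct SeCache { mat s; mat z1; mat a1; mat z; bool identity; };

static cube se_fwd(const cube& x, const mat& W1, const vec& b1,
                   const mat& W2, const vec& b2, bool identity, SeCache& cc) {
  cc.identity = identity;
  if (identity) return x;
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  mat s(C, B);
  for (int b = 0; b < B; ++b) s.col(b) = mean(x.slice(b), 1);
  mat z1 = W1 * s; z1.each_col() += b1;
  mat a1 = clamp(z1, 0.0, datum::inf);
  mat z2 = W2 * a1; z2.each_col() += b2;
  mat z = 1.0 / (1.0 + exp(-z2));
  cc.s = s; cc.z1 = z1; cc.a1 = a1; cc.z = z;
  cube y(C, L, B);
  for (int b = 0; b < B; ++b) y.slice(b) = x.slice(b).each_col() % z.col(b);
  return y;
}

static cube se_bwd(const cube& x, const cube& gy, const SeCache& cc,
                   const mat& W1, const mat& W2,
                   mat& gW1, vec& gb1, mat& gW2, vec& gb2) {
  if (cc.identity) return gy;
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  mat gz(C, B);
  cube gx(C, L, B);
  for (int b = 0; b < B; ++b) {
    gz.col(b) = sum(gy.slice(b) % x.slice(b), 1);
    gx.slice(b) = gy.slice(b).each_col() % cc.z.col(b);
  }
  mat gz2 = gz % cc.z % (1.0 - cc.z);
  gW2 += gz2 * cc.a1.t();
  gb2 += sum(gz2, 1);
  mat ga1 = W2.t() * gz2;
  mat gz1 = ga1 % conv_to<mat>::from(cc.z1 > 0.0);
  gW1 += gz1 * cc.s.t();
  gb1 += sum(gz1, 1);
  mat gs = W1.t() * gz1;
  for (int b = 0; b < B; ++b)
    gx.slice(b).each_col() += gs.col(b) / (double)L;
  return gx;
}

static cube conv_fwd(const cube& x, const mat& W, const vec& b, int k,
                     int stride, int pad) {
  const int B = x.n_slices, L = x.n_cols;
  const int Lout = (L + 2 * pad - k) / stride + 1;
  mat P = im2col1d_batch(x, k, stride, pad, Lout);
  mat Y = W * P;
  Y.each_col() += b;
  cube y(W.n_rows, Lout, B);
  for (int s = 0; s < B; ++s)
    y.slice(s) = Y.cols((size_t)s * Lout, (size_t)(s + 1) * Lout - 1);
  return y;
}

static cube conv_bwd(const cube& x, const mat& W, const cube& gy, int k,
                     int stride, int pad, mat& gW, vec& gb) {
  const int B = x.n_slices, L = x.n_cols, Cin = x.n_rows;
  const int Lout = gy.n_cols;
  mat P = im2col1d_batch(x, k, stride, pad, Lout);
  mat GY(gy.n_rows, (size_t)Lout * B);
  for (int s = 0; s < B; ++s)
    GY.cols((size_t)s * Lout, (size_t)(s + 1) * Lout - 1) = gy.slice(s);
  gW += GY * P.t();
  gb += sum(GY, 1);
  mat gP = W.t() * GY;
  cube gx(Cin, L, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    mat& gxs = gx.slice(s);
    for (int t = 0; t < Lout; ++t) {
      const int start = t * stride - pad;
      const size_t col = (size_t)s * Lout + t;
      for (int kk = 0; kk < k; ++kk) {
        const int idx = start + kk;
        if (idx >= 0 && idx < L)
          gxs.col(idx) += gP.submat(kk * Cin, col, (kk + 1) * Cin - 1, col);
      }
    }
  }
  return gx;
}

struct RbCache {
  cube x, c1, b1y, s1y, r1, c2, b2y, s2y, scy, out;
  BnCache bn1, bn2;
  SeCache se1, se2;
};

static std::vector<RbCache> rb_caches;   // handle-indexed scratch store

static mat getm(const Rcpp::List& p, const char* nm) {
  return Rcpp::as<mat>(p[nm]);
}
static vec getv(const Rcpp::List& p, const char* nm) {
  return Rcpp::as<vec>(p[nm]);
}

// [[Rcpp::export]]
Rcpp::List cpp_resblock_fwd(const arma::cube& x, const Rcpp::List& prm,
                            bool training, int stride, bool keep) {
  RbCache cc;
  const bool hasSc = Rcpp::as<bool>(prm["has_sc"]);
  const bool se1id = Rcpp::as<bool>(prm["se1_identity"]);
  const bool se2id = Rcpp::as<bool>(prm["se2_identity"]);
  const double eps = Rcpp::as<double>(prm["eps"]);
  const int k = 3, pad = 1;
  cc.x = x;
  cc.c1 = conv_fwd(x, getm(prm, "W1"), getv(prm, "bb1"), k, stride, pad);
  cc.b1y = bn_fwd(cc.c1, getv(prm, "gamma1"), getv(prm, "beta1"),
                  getv(prm, "rm1"), getv(prm, "rv1"), eps, training, cc.bn1);
  cc.s1y = se_fwd(cc.b1y,
                  se1id ? mat() : getm(prm, "se1W1"),
                  se1id ? vec() : getv(prm, "se1b1"),
                  se1id ? mat() : getm(prm, "se1W2"),
                  se1id ? vec() : getv(prm, "se1b2"), se1id, cc.se1);
  cc.r1 = clamp(cc.s1y, 0.0, datum::inf);
  cc.c2 = conv_fwd(cc.r1, getm(prm, "W2"), getv(prm, "bb2"), k, 1, pad);
  cc.b2y = bn_fwd(cc.c2, getv(prm, "gamma2"), getv(prm, "beta2"),
                  getv(prm, "rm2"), getv(prm, "rv2"), eps, training, cc.bn2);
  cc.s2y = se_fwd(cc.b2y,
                  se2id ? mat() : getm(prm, "se2W1"),
                  se2id ? vec() : getv(prm, "se2b1"),
                  se2id ? mat() : getm(prm, "se2W2"),
                  se2id ? vec() : getv(prm, "se2b2"), se2id, cc.se2);
  cube presum;
  if (hasSc) {
    cc.scy = conv_fwd(x, getm(prm, "Wsc"), getv(prm, "bsc"), 1, stride, 0);
    presum = cc.s2y + cc.scy;
  } else {
    presum = cc.s2y + x;
  }
  cc.out = clamp(presum, 0.0, datum::inf);
  int handle = -1;
  if (keep) {
    rb_caches.push_back(std::move(cc));
    handle = (int)rb_caches.size() - 1;
  }
  Rcpp::List ret = Rcpp::List::create(
    Rcpp::Named("out") = keep ? rb_caches.back().out : cc.out,
    Rcpp::Named("presum") = presum,
    Rcpp::Named("handle") = handle);
  if (training) {
    const BnCache& b1 = keep ? rb_caches.back().bn1 : cc.bn1;
    const BnCache& b2 = keep ? rb_caches.back().bn2 : cc.bn2;
    ret["bn1_mu"] = b1.mu; ret["bn1_var"] = b1.var;
    ret["bn2_mu"] = b2.mu; ret["bn2_var"] = b2.var;
  }
  return ret;
}

// [[Rcpp::export]]
Rcpp::List cpp_resblock_bwd(int handle, const Rcpp::List& prm,
                            const arma::cube& gy, int stride) {
  RbCache& cc = rb_caches[handle];
  const bool hasSc = Rcpp::as<bool>(prm["has_sc"]);
  const int k = 3, pad = 1;
  cube g = gy % conv_to<cube>::from(cc.out > 0.0);
  cube gskip = g;
  mat gse2W1, gse2W2, gse1W1, gse1W2;
  vec gse2b1, gse2b2, gse1b1, gse1b2;
  if (!cc.se2.identity) {
    gse2W1 = zeros<mat>(getm(prm, "se2W1").n_rows, getm(prm, "se2W1").n_cols);
    gse2W2 = zeros<mat>(getm(prm, "se2W2").n_rows, getm(prm, "se2W2").n_cols);
    gse2b1 = zeros<vec>(getv(prm, "se2b1").n_elem);
    gse2b2 = zeros<vec>(getv(prm, "se2b2").n_elem);
    g = se_bwd(cc.b2y, g, cc.se2, getm(prm, "se2W1"), getm(prm, "se2W2"),
               gse2W1, gse2b1, gse2W2, gse2b2);
  }
  vec ggamma2 = zeros<vec>(getv(prm, "gamma2").n_elem);
  vec gbeta2 = zeros<vec>(ggamma2.n_elem);
  g = bn_bwd(g, cc.bn2, getv(prm, "gamma2"), ggamma2, gbeta2);
  mat gW2 = zeros<mat>(getm(prm, "W2").n_rows, getm(prm, "W2").n_cols);
  vec gb2 = zeros<vec>(gW2.n_rows);
  g = conv_bwd(cc.r1, getm(prm, "W2"), g, k, 1, pad, gW2, gb2);
  g %= conv_to<cube>::from(cc.s1y > 0.0);
  if (!cc.se1.identity) {
    gse1W1 = zeros<mat>(getm(prm, "se1W1").n_rows, getm(prm, "se1W1").n_cols);
    gse1W2 = zeros<mat>(getm(prm, "se1W2").n_rows, getm(prm, "se1W2").n_cols);
    gse1b1 = zeros<vec>(getv(prm, "se1b1").n_elem);
    gse1b2 = zeros<vec>(getv(prm, "se1b2").n_elem);
    g = se_bwd(cc.b1y, g, cc.se1, getm(prm, "se1W1"), getm(prm, "se1W2"),
               gse1W1, gse1b1, gse1W2, gse1b2);
  }
  vec ggamma1 = zeros<vec>(getv(prm, "gamma1").n_elem);
  vec gbeta1 = zeros<vec>(ggamma1.n_elem);
  g = bn_bwd(g, cc.bn1, getv(prm, "gamma1"), ggamma1, gbeta1);
  mat gW1 = zeros<mat>(getm(prm, "W1").n_rows, getm(prm, "W1").n_cols);
  vec gb1 = zeros<vec>(gW1.n_rows);
  cube gx = conv_bwd(cc.x, getm(prm, "W1"), g, k, stride, pad, gW1, gb1);
  Rcpp::List ret = Rcpp::List::create(
    Rcpp::Named("gx") = gx,   // placeholder, reassigned below
    Rcpp::Named("gW1") = gW1, Rcpp::Named("gb1") = gb1,
    Rcpp::Named("ggamma1") = ggamma1, Rcpp::Named("gbeta1") = gbeta1,
    Rcpp::Named("gW2") = gW2, Rcpp::Named("gb2") = gb2,
    Rcpp::Named("ggamma2") = ggamma2, Rcpp::Named("gbeta2") = gbeta2);
  if (hasSc) {
    mat gWsc = zeros<mat>(getm(prm, "Wsc").n_rows, getm(prm, "Wsc").n_cols);
    vec gbsc = zeros<vec>(gWsc.n_rows);
    gx += conv_bwd(cc.x, getm(prm, "Wsc"), gskip, 1, stride, 0, gWsc, gbsc);
    ret["gWsc"] = gWsc; ret["gbsc"] = gbsc;
  } else {
    gx += gskip;
  }
  ret["gx"] = gx;
  if (!cc.se1.identity) {
    ret["gse1W1"] = gse1W1; ret["gse1b1"] = gse1b1;
    ret["gse1W2"] = gse1W2; ret["gse1b2"] = gse1b2;
  }
  if (!cc.se2.identity) {
    ret["gse2W1"] = gse2W1; ret["gse2b1"] = gse2b1;
    ret["gse2W2"] = gse2W2; ret["gse2b2"] = gse2b2;
  }
  return ret;
}

// [[Rcpp::export]]
void cpp_resblock_clear() { rb_caches.clear(); }

// Fused multi-scale front end: per branch j, conv(1 -> c_j, k_j, same
// padding) + ReLU + non-overlapping max-pool(w), branch outputs stacked
// channelwise. Returns the pooled map and the argmax positions; because
// pooling selects a single position per window and ReLU's gradient mask
// is recoverable from the pooled output sign, the backward pass needs no
// full-length intermediates.
// [[Rcpp::export]]
Rcpp::List cpp_msfront_fwd(const arma::cube& x, const Rcpp::List& Ws,
                           const Rcpp::List& bs, const arma::ivec& ks,
                           int poolw) {
  const int B = x.n_slices, L = x.n_cols;
  const int nb = ks.n_elem;
  const int Lout = L / poolw;
  int Ctot = 0;
  std::vector<mat> W(nb);
  std::vector<vec> b(nb);
  for (int j = 0; j < nb; ++j) {
    W[j] = Rcpp::as<mat>(Ws[j]);
    b[j] = Rcpp::as<vec>(bs[j]);
    Ctot += W[j].n_rows;
  }
  cube y(Ctot, Lout, B), idx(Ctot, Lout, B);
  for (int s = 0; s < B; ++s) {
    const rowvec xs = x.slice(s).row(0);
    int coff = 0;
    for (int j = 0; j < nb; ++j) {
      const int k = ks[j], pad = (k - 1) / 2, C = W[j].n_rows;
      mat P(k, L, fill::zeros);
      for (int kk = 0; kk < k; ++kk) {
        const int lo = std::max(0, pad - kk), hi = std::min(L, L + pad - kk);
        for (int t = lo; t < hi; ++t) P(kk, t) = xs(t - pad + kk);
      }
      mat Y = W[j] * P;          // C x L
      Y.each_col() += b[j];
      Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
      for (int t = 0; t < Lout; ++t) {
        const int start = t * poolw;
        for (int c = 0; c < C; ++c) {
          double best = Y(c, start);
          int bi = start;
          for (int q = 1; q < poolw; ++q)
            if (Y(c, start + q) > best) { best = Y(c, start + q); bi = start + q; }
          y(coff + c, t, s) = best;
          idx(coff + c, t, s) = bi;
        }
      }
      coff += C;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
Rcpp::List cpp_msfront_bwd(const arma::cube& x, const arma::cube& y,
                           const arma::cube& idx, const arma::cube& gy,
                           const arma::ivec& ks,
                           const Rcpp::IntegerVector& chans) {
  const int B = x.n_slices, L = x.n_cols;
  const int nb = ks.n_elem;
  const int Lout = gy.n_cols;
  Rcpp::List gWs(nb), gbs(nb);
  std::vector<mat> gW(nb);
  std::vector<vec> gb(nb);
  for (int j = 0; j < nb; ++j) {
    gW[j] = mat(chans[j], ks[j], fill::zeros);
    gb[j] = vec(chans[j], fill::zeros);
  }
  for (int s = 0; s < B; ++s) {
    const rowvec xs = x.slice(s).row(0);
    int coff = 0;
    for (int j = 0; j < nb; ++j) {
      const int k = ks[j], pad = (k - 1) / 2, C = chans[j];
      for (int t = 0; t < Lout; ++t) {
        for (int c = 0; c < C; ++c) {
          const double g = gy(coff + c, t, s);
          if (g == 0.0 || y(coff + c, t, s) <= 0.0) continue;
          const int pos = (int)idx(coff + c, t, s);
          gb[j](c) += g;
          for (int kk = 0; kk < k; ++kk) {
            const int xi = pos - pad + kk;
            if (xi >= 0 && xi < L) gW[j](c, kk) += g * xs(xi);
          }
        }
      }
      coff += C;
    }
  }
  for (int j = 0; j < nb; ++j) {
    gWs[j] = gW[j];
    gbs[j] = gb[j];
  }
  return Rcpp::List::create(Rcpp::Named("gW") = gWs,
                            Rcpp::Named("gb") = gbs);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool1d_fwd(const arma::cube& x, int w, int stride) {
  const int B = x.n_slices, L = x.n_cols, C = x.n_rows;
  const int Lout = (L - w) / stride + 1;
  cube y(C, Lout, B);
  cube idx(C, Lout, B);   // argmax positions (0-based), stored as double
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < Lout; ++t) {
      const int start = t * stride;
      for (int c = 0; c < C; ++c) {
        double best = x(c, start, s);
        int bi = start;
        for (int j = 1; j < w; ++j) {
          const double v = x(c, start + j, s);
          if (v > best) { best = v; bi = start + j; }
        }
        y(c, t, s) = best;
        idx(c, t, s) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool1d_bwd(const arma::cube& gy, const arma::cube& idx,
                             int L) {
  const int B = gy.n_slices, Lout = gy.n_cols, C = gy.n_rows;
  cube gx(C, L, B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < Lout; ++t)
      for (int c = 0; c < C; ++c)
        gx(c, (int)idx(c, t, s), s) += gy(c, t, s);
  return gx;
}
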