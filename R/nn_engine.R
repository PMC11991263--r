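# ---------------------------------------------------------------------
# Minimal 1-D network engine: parameter containers, forward/backward
# passes for conv / batch-norm / SE attention / residual blocks / MLP,
# softmax cross-entropy, and SGD with momentum. Activations are arrays of
# shape (channels, length, batch); convolutions run through the compiled
# im2col kernels in src/nnops.cpp. Gradients accumulate into the shared
# parameter environments, which is what makes cross-stream weight sharing
# work: the two streams hold references to the same environments.
# ---------------------------------------------------------------------

.new_param <- function(pnames) {
  p <- new.env(parent = emptyenv())
  p$pnames <- pnames
  p
}

.param_conv <- function(cin, cout, k) {
  p <- .new_param(c("W", "b"))
  p$kind <- "conv"; p$k <- as.integer(k)
  p$cin <- cin; p$cout <- cout
  p$W <- matrix(rnorm(cout * cin * k, 0, sqrt(2 / (cin * k))), cout, cin * k)
  p$b <- numeric(cout)
  p$gW <- 0 * p$W; p$gb <- numeric(cout)
  p$vW <- 0 * p$W; p$vb <- numeric(cout)
  p
}

.param_linear <- function(fin, fout) {
  p <- .new_param(c("W", "b"))
  p$kind <- "linear"
  p$W <- matrix(rnorm(fout * fin, 0, sqrt(2 / fin)), fout, fin)
  p$b <- numeric(fout)
  p$gW <- 0 * p$W; p$gb <- numeric(fout)
  p$vW <- 0 * p$W; p$vb <- numeric(fout)
  p
}

.param_bn <- function(c) {
  p <- .new_param(c("gamma", "beta"))
  p$kind <- "bn"
  p$gamma <- rep(1, c); p$beta <- numeric(c)
  p$ggamma <- numeric(c); p$gbeta <- numeric(c)
  p$vgamma <- numeric(c); p$vbeta <- numeric(c)
  p$running_mean <- numeric(c); p$running_var <- rep(1, c)
  # second set of running buffers: when two streams share normalization
  # *parameters*, each stream still tracks its own activation statistics
  # (the raw and differenced streams have very different scales)
  p$running_mean2 <- numeric(c); p$running_var2 <- rep(1, c)
  p$mom <- 0.1; p$eps <- 1e-5
  p
}

.param_se <- function(c, reduction) {
  cr <- max(1L, c %/% reduction)
  p <- .new_param(c("W1", "b1", "W2", "b2"))
  p$kind <- "se"
  p$W1 <- matrix(rnorm(cr * c, 0, sqrt(2 / c)), cr, c)
  p$b1 <- numeric(cr)
  p$W2 <- matrix(rnorm(c * cr, 0, sqrt(2 / cr)), c, cr)
  p$b2 <- numeric(c)
  for (nm in p$pnames) {
    assign(paste0("g", nm), 0 * get(nm, p), p)
    assign(paste0("v", nm), 0 * get(nm, p), p)
  }
  p
}

# ---- elementary layers ------------------------------------------------

.conv_fwd <- function(x, p, stride = 1L, pad = (p$k - 1L) %/% 2L) {
  y <- cpp_conv1d_fwd(x, p$W, p$b, p$k, stride, pad)
  list(out = y, cache = list(x = x, stride = stride, pad = pad))
}

.conv_bwd <- function(p, cache, gy) {
  r <- cpp_conv1d_bwd(cache$x, p$W, gy, p$k, cache$stride, cache$pad)
  p$gW <- p$gW + r$gW
  p$gb <- p$gb + as.vector(r$gb)
  r$gx
}

.relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, cache = m)
}
.relu_bwd <- function(cache, gy) gy * cache

.pool_fwd <- function(x, w, stride = w) {
  r <- cpp_maxpool1d_fwd(x, w, stride)
  list(out = r$y, cache = list(idx = r$idx, L = dim(x)[2L]))
}
.pool_bwd <- function(cache, gy) cpp_maxpool1d_bwd(gy, cache$idx, cache$L)

.bn_fwd <- function(x, p, training) {
  d <- dim(x)
  C <- d[1L]; n <- d[2L] * d[3L]
  xm <- matrix(x, C)
  if (training && n > 1L) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    p$running_mean <- (1 - p$mom) * p$running_mean + p$mom * mu
    p$running_var <- (1 - p$mom) * p$running_var + p$mom * v * n / (n - 1L)
    used_batch <- TRUE
  } else {
    mu <- p$running_mean
    v <- p$running_var
    xc <- xm - mu
    used_batch <- FALSE
  }
  istd <- 1 / sqrt(v + p$eps)
  xhat <- xc * istd
  y <- xhat * p$gamma + p$beta
  list(out = array(y, d),
       cache = list(xhat = xhat, istd = istd, d = d, batch = used_batch))
}

.bn_bwd <- function(p, cache, gy) {
  d <- cache$d
  gym <- matrix(gy, d[1L])
  p$gbeta <- p$gbeta + rowSums(gym)
  p$ggamma <- p$ggamma + rowSums(gym * cache$xhat)
  gxhat <- gym * p$gamma
  if (cache$batch) {
    gx <- cache$istd *
      (gxhat - rowMeans(gxhat) - cache$xhat * rowMeans(gxhat * cache$xhat))
  } else {
    gx <- gxhat * cache$istd
  }
  array(gx, d)
}

.se_fwd <- function(x, p) {
  if (identical(p$kind, "se_identity"))
    return(list(out = x, cache = NULL))
  d <- dim(x)
  C <- d[1L]; L <- d[2L]; B <- d[3L]
  s <- colMeans(array(aperm(x, c(2L, 1L, 3L)), c(L, C * B)))
  dim(s) <- c(C, B)
  z1 <- p$W1 %*% s + p$b1
  a1 <- z1 * (z1 > 0)
  z2 <- p$W2 %*% a1 + p$b2
  z <- 1 / (1 + exp(-z2))
  zfull <- aperm(array(z, c(C, B, L)), c(1L, 3L, 2L))
  y <- x * zfull
  list(out = y, cache = list(x = x, zfull = zfull, s = s, z1 = z1,
                             a1 = a1, z = z, d = d))
}

.se_bwd <- function(p, cache, gy) {
  if (identical(p$kind, "se_identity")) return(gy)
  d <- cache$d
  C <- d[1L]; L <- d[2L]; B <- d[3L]
  z <- cache$z
  gz <- colSums(array(aperm(gy * cache$x, c(2L, 1L, 3L)), c(L, C * B)))
  dim(gz) <- c(C, B)
  gx <- gy * cache$zfull
  gz2 <- gz * z * (1 - z)
  p$gW2 <- p$gW2 + gz2 %*% t(cache$a1)
  p$gb2 <- p$gb2 + rowSums(gz2)
  ga1 <- t(p$W2) %*% gz2
  gz1 <- ga1 * (cache$z1 > 0)
  p$gW1 <- p$gW1 + gz1 %*% t(cache$s)
  p$gb1 <- p$gb1 + rowSums(gz1)
  gs <- t(p$W1) %*% gz1
  gx + aperm(array(gs / L, c(C, B, L)), c(1L, 3L, 2L))
}

.lin_fwd <- function(x, p) {
  list(out = p$W %*% x + p$b, cache = x)
}
.lin_bwd <- function(p, cache, gy) {
  p$gW <- p$gW + gy %*% t(cache)
  p$gb <- p$gb + rowSums(gy)
  t(p$W) %*% gy
}

.drop_fwd <- function(x, rate, training) {
  if (!training || rate <= 0)
    return(list(out = x, cache = NULL))
  m <- array((runif(length(x)) >= rate) / (1 - rate), dim(x) %||% length(x))
  list(out = x * m, cache = m)
}
.drop_bwd <- function(cache, gy) if (is.null(cache)) gy else gy * cache

`%||%` <- function(a, b) if (is.null(a)) b else a

.cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L] + db[1L], da[2L], da[3L]))
  out[seq_len(da[1L]), , ] <- a
  out[da[1L] + seq_len(db[1L]), , ] <- b
  out
}

# global pooling over length, per channel per sample:
#   "avg"  - arithmetic mean
#   "max"  - hard maximum (gradient reaches only the argmax)
#   "pnorm" - soft maximum (mean(a^p))^(1/p) on the nonnegative
#             activations; approximates the maximum while keeping dense
#             gradients weighted toward the strongest responses
.gpool_fwd <- function(x, type = "avg", p = 6) {
  if (type == "avg") return(.gap_fwd(x))
  d <- dim(x)
  if (type == "max") {
    r <- cpp_maxpool1d_fwd(x, d[2L], d[2L])
    g <- matrix(r$y, d[1L], d[3L])
    return(list(out = g, cache = list(type = "max", idx = r$idx, d = d)))
  }
  xp <- x^p
  mp <- .gap_fwd(xp)$out
  out <- mp^(1 / p)
  list(out = out, cache = list(type = "pnorm", x = x, out = out, d = d,
                               p = p))
}
.gpool_bwd <- function(cache, gy) {
  if (is.null(cache$type)) return(.gap_bwd(cache, gy))
  d <- cache$d
  if (cache$type == "max") {
    gyc <- array(gy, c(d[1L], 1L, d[3L]))
    return(cpp_maxpool1d_bwd(gyc, cache$idx, d[2L]))
  }
  p <- cache$p
  # d out / d x_i = (1/L) x_i^(p-1) out^(1-p)
  fac <- gy * ifelse(cache$out > 0, cache$out^(1 - p), 0) / d[2L]
  cache$x^(p - 1L) * aperm(array(fac, c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
}

.gap_fwd <- function(x) {
  d <- dim(x)
  g <- colMeans(array(aperm(x, c(2L, 1L, 3L)), c(d[2L], d[1L] * d[3L])))
  dim(g) <- c(d[1L], d[3L])
  list(out = g, cache = d)
}
.gap_bwd <- function(cache, gy) {
  d <- cache
  aperm(array(gy / d[2L], c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
}

.softmax_xent <- function(logits, labels) {
  K <- nrow(logits); B <- ncol(logits)
  m <- apply(logits, 2L, max)
  e <- exp(logits - rep(m, each = K))
  pr <- e / rep(colSums(e), each = K)
  ix <- cbind(labels, seq_len(B))
  loss <- -mean(log(pmax(pr[ix], 1e-300)))
  g <- pr
  g[ix] <- g[ix] - 1
  list(loss = loss, probs = pr, grad = g / B)
}

# ---- residual blocks --------------------------------------------------

# Res_Basic / Res_Down: conv -> norm -> SE -> activation -> conv -> norm
# -> SE, plus an identity (Res_Basic) or 1x1-convolution (Res_Down)
# shortcut; the block output adds the two paths (y = F(x) + shortcut(x)),
# followed by an activation inside the network. The production path runs
# fused in compiled code (cpp_resblock_fwd/_bwd); the interpreter
# implementation below (.resblock_fwd_r) is retained as the reference.

.rb_pack <- function(bp, alt = FALSE) {
  se1id <- identical(bp$se1$kind, "se_identity")
  se2id <- identical(bp$se2$kind, "se_identity")
  rmf <- if (alt) "running_mean2" else "running_mean"
  rvf <- if (alt) "running_var2" else "running_var"
  out <- list(W1 = bp$conv1$W, bb1 = bp$conv1$b,
              gamma1 = bp$bn1$gamma, beta1 = bp$bn1$beta,
              rm1 = get(rmf, bp$bn1), rv1 = get(rvf, bp$bn1),
              W2 = bp$conv2$W, bb2 = bp$conv2$b,
              gamma2 = bp$bn2$gamma, beta2 = bp$bn2$beta,
              rm2 = get(rmf, bp$bn2), rv2 = get(rvf, bp$bn2),
              eps = bp$bn1$eps, has_sc = !is.null(bp$sc),
              se1_identity = se1id, se2_identity = se2id)
  if (!se1id)
    out[c("se1W1", "se1b1", "se1W2", "se1b2")] <-
      list(bp$se1$W1, bp$se1$b1, bp$se1$W2, bp$se1$b2)
  if (!se2id)
    out[c("se2W1", "se2b1", "se2W2", "se2b2")] <-
      list(bp$se2$W1, bp$se2$b1, bp$se2$W2, bp$se2$b2)
  if (!is.null(bp$sc)) {
    out$Wsc <- bp$sc$W
    out$bsc <- bp$sc$b
  }
  out
}

.resblock_fwd <- function(bp, x, training, stride = 1L, keep = training,
                          alt = FALSE) {
  prm <- .rb_pack(bp, alt)
  r <- cpp_resblock_fwd(x, prm, training, as.integer(stride), keep = keep)
  if (training) {
    n <- ((dim(x)[2L] - 1L) %/% stride + 1L) * dim(x)[3L]  # per-channel n
    if (n > 1) {
      adj <- n / (n - 1)
      rmf <- if (alt) "running_mean2" else "running_mean"
      rvf <- if (alt) "running_var2" else "running_var"
      for (b in list(list(bp$bn1, r$bn1_mu, r$bn1_var),
                     list(bp$bn2, r$bn2_mu, r$bn2_var))) {
        p <- b[[1L]]
        assign(rmf, (1 - p$mom) * get(rmf, p) + p$mom * as.vector(b[[2L]]), p)
        assign(rvf, (1 - p$mom) * get(rvf, p) +
                 p$mom * as.vector(b[[3L]]) * adj, p)
      }
    }
  }
  list(out = r$out, presum = r$presum,
       cache = list(handle = r$handle, stride = as.integer(stride)))
}

.resblock_bwd <- function(bp, cache, gy) {
  prm <- .rb_pack(bp)
  r <- cpp_resblock_bwd(cache$handle, prm, gy, cache$stride)
  bp$conv1$gW <- bp$conv1$gW + r$gW1
  bp$conv1$gb <- bp$conv1$gb + as.vector(r$gb1)
  bp$bn1$ggamma <- bp$bn1$ggamma + as.vector(r$ggamma1)
  bp$bn1$gbeta <- bp$bn1$gbeta + as.vector(r$gbeta1)
  bp$conv2$gW <- bp$conv2$gW + r$gW2
  bp$conv2$gb <- bp$conv2$gb + as.vector(r$gb2)
  bp$bn2$ggamma <- bp$bn2$ggamma + as.vector(r$ggamma2)
  bp$bn2$gbeta <- bp$bn2$gbeta + as.vector(r$gbeta2)
  if (!is.null(bp$sc)) {
    bp$sc$gW <- bp$sc$gW + r$gWsc
    bp$sc$gb <- bp$sc$gb + as.vector(r$gbsc)
  }
  for (senm in c("se1", "se2")) {
    p <- bp[[senm]]
    if (identical(p$kind, "se_identity")) next
    p$gW1 <- p$gW1 + r[[paste0("g", senm, "W1")]]
    p$gb1 <- p$gb1 + as.vector(r[[paste0("g", senm, "b1")]])
    p$gW2 <- p$gW2 + r[[paste0("g", senm, "W2")]]
    p$gb2 <- p$gb2 + as.vector(r[[paste0("g", senm, "b2")]])
  }
  r$gx
}

.resblock_fwd_r <- function(bp, x, training, stride = 1L) {
  c1 <- .conv_fwd(x, bp$conv1, stride = stride)
  b1 <- .bn_fwd(c1$out, bp$bn1, training)
  s1 <- .se_fwd(b1$out, bp$se1)
  r1 <- .relu_fwd(s1$out)
  c2 <- .conv_fwd(r1$out, bp$conv2)
  b2 <- .bn_fwd(c2$out, bp$bn2, training)
  s2 <- .se_fwd(b2$out, bp$se2)
  sc <- if (!is.null(bp$sc)) .conv_fwd(x, bp$sc, stride = stride, pad = 0L)
  presum <- s2$out + if (is.null(sc)) x else sc$out
  r2 <- .relu_fwd(presum)
  list(out = r2$out, presum = presum,
       cache = list(c1 = c1$cache, b1 = b1$cache, s1 = s1$cache,
                    r1 = r1$cache, c2 = c2$cache, b2 = b2$cache,
                    s2 = s2$cache, sc = if (is.null(sc)) NULL else sc$cache,
                    r2 = r2$cache))
}

.resblock_bwd_r <- function(bp, cache, gy) {
  g <- .relu_bwd(cache$r2, gy)
  gskip <- g
  g <- .se_bwd(bp$se2, cache$s2, g)
  g <- .bn_bwd(bp$bn2, cache$b2, g)
  g <- .conv_bwd(bp$conv2, cache$c2, g)
  g <- .relu_bwd(cache$r1, g)
  g <- .se_bwd(bp$se1, cache$s1, g)
  g <- .bn_bwd(bp$bn1, cache$b1, g)
  gx <- .conv_bwd(bp$conv1, cache$c1, g)
  gx + if (is.null(bp$sc)) gskip else .conv_bwd(bp$sc, cache$sc, gskip)
}

.new_resbasic <- function(c, reduction) {
  list(conv1 = .param_conv(c, c, 3L), bn1 = .param_bn(c),
       se1 = .param_se(c, reduction),
       conv2 = .param_conv(c, c, 3L), bn2 = .param_bn(c),
       se2 = .param_se(c, reduction), sc = NULL)
}

.new_resdown <- function(cin, cout, reduction, stride = 1L) {
  list(conv1 = .param_conv(cin, cout, 3L), bn1 = .param_bn(cout),
       se1 = .param_se(cout, reduction),
       conv2 = .param_conv(cout, cout, 3L), bn2 = .param_bn(cout),
       se2 = .param_se(cout, reduction),
       sc = .param_conv(cin, cout, 1L), stride = as.integer(stride))
}

# ---- bookkeeping ------------------------------------------------------

.collect_params <- function(x) {
  if (is.environment(x)) return(list(x))
  if (is.list(x)) return(do.call(c, c(lapply(x, .collect_params), list(list()))))
  list()
}

.unique_params <- function(model) unique(.collect_params(model$params))

.n_params <- function(model) {
  sum(vapply(.unique_params(model), function(p)
    sum(vapply(p$pnames, function(nm) length(get(nm, p)), 0)), 0))
}

.zero_grads <- function(params) {
  for (p in params)
    for (nm in p$pnames)
      assign(paste0("g", nm), 0 * get(paste0("g", nm), p), p)
  invisible(NULL)
}

.sgd_step <- function(params, lr, momentum) {
  for (p in params) {
    for (nm in p$pnames) {
      g <- get(paste0("g", nm), p)
      v <- momentum * get(paste0("v", nm), p) - lr * g
      assign(paste0("v", nm), v, p)
      assign(nm, get(nm, p) + v, p)
    }
  }
  invisible(NULL)
}
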