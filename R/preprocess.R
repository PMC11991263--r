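#' Min-max normalization to \[0, 1\]
#'
#' Linearly rescales a vector so its minimum maps to 0 and its maximum to
#' 1: `(x - min) / (max - min)`. A monotone transform, so order statistics
#' are preserved.
#'
#' @param y numeric vector, length >= 2, with `max(y) > min(y)`.
#' @return vector of the same length with min 0 and max 1.
#' @examples
#' minMaxNormalize(c(2, 4, 6))   # 0, 0.5, 1
#' @export
minMaxNormalize <- function(y) {
  if (length(y) < 2L)
    stop("minMaxNormalize: input must have length >= 2", call. = FALSE)
  r <- range(y)
  if (r[1L] == r[2L])
    stop("minMaxNormalize: degenerate input (constant vector, max == min)",
         call. = FALSE)
  (y - r[1L]) / (r[2L] - r[1L])
}

#' Savitzky-Golay smoothing coefficients
#'
#' Solves the sliding-window least-squares problem: for window positions
#' `-m..m` and polynomial order `p`, forms the Vandermonde design `X` and
#' the projection `H = X (X'X)^{-1} X'`. The central row of `H` gives the
#' convolution weights applied at interior points; the leading/trailing
#' rows are used at the edges (polynomial-extrapolation edge handling), so
#' polynomials of degree <= `p` are reproduced exactly end-to-end.
#'
#' The central weights sum to 1 and are symmetric (`c_i = c_{-i}`).
#'
#' @param order polynomial order `p >= 0`.
#' @param window odd window length `2m + 1 > p`.
#' @return an [SGFilter-class]
#' @examples
#' sgCoefficients(0, 3)@coefficients   # 1/3, 1/3, 1/3 (moving average)
#' @export
sgCoefficients <- function(order, window) {
  order <- as.integer(order); window <- as.integer(window)
  if (window %% 2L == 0L)
    stop("sgCoefficients: window must be odd", call. = FALSE)
  if (window <= order)
    stop("sgCoefficients: window must exceed order", call. = FALSE)
  m <- (window - 1L) %/% 2L
  X <- outer(seq(-m, m), 0:order, `^`)
  H <- X %*% solve(crossprod(X), t(X))
  new("SGFilter", order = order, window = window,
      coefficients = H[m + 1L, ], projection = H)
}

#' Apply a Savitzky-Golay filter
#'
#' Interior points are smoothed by convolution with the central
#' least-squares weights; the first and last `m` points use the full
#' window projection anchored at the corresponding edge, so degree-<=order
#' polynomials are fixed points everywhere, edges included.
#'
#' @param y numeric vector with `length(y) >= window`.
#' @param filt an [SGFilter-class] from [sgCoefficients()], or `NULL` to
#'   build one from `order`/`window`.
#' @param order,window used when `filt` is `NULL`.
#' @return smoothed vector, same length as `y`.
#' @export
sgSmooth <- function(y, filt = NULL, order = 5, window = 7) {
  if (is.null(filt)) filt <- sgCoefficients(order, window)
  stopifnot(is(filt, "SGFilter"))
  n <- length(y)
  w <- filt@window
  if (n < w)
    stop(sprintf("sgSmooth: input length %d shorter than window %d", n, w),
         call. = FALSE)
  m <- (w - 1L) %/% 2L
  out <- numeric(n)
  # interior: convolution of Eq. y_k = sum_i c_i x_{k+i}
  cf <- filt@coefficients
  for (i in seq_len(w))
    out[(m + 1L):(n - m)] <- out[(m + 1L):(n - m)] +
      cf[i] * y[i:(n - w + i)]
  # edges: project the first/last full window and keep the outer rows
  if (m > 0L) {
    out[1:m] <- (filt@projection %*% y[1:w])[1:m]
    out[(n - m + 1L):n] <- (filt@projection %*% y[(n - w + 1L):n])[(m + 2L):w]
  }
  out
}

# --- wavelet denoising -------------------------------------------------
# Periodized orthonormal DWT with the sym4 filter bank (8 taps), pyramid
# algorithm, universal soft threshold on the detail coefficients. The
# transform is orthonormal, so shrinking coefficients can only decrease
# signal energy (Parseval).

# sym4 (least-asymmetric Daubechies, 4 vanishing moments) low-pass
# decomposition filter.
.sym4_lo <- c(-0.07576571478927333, -0.02963552764599851,
              0.49761866763201545, 0.80373875180591614,
              0.29785779560527736, -0.09921954357684722,
              -0.01260396726203783, 0.03222310060404270)

.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  k <- length(lo)
  # periodized convolution then downsample by 2
  idx <- outer(seq(0, n - 2, by = 2), seq_len(k) - 1L, `+`) %% n + 1L
  xm <- matrix(x[idx], nrow = n %/% 2L)
  list(a = as.vector(xm %*% lo), d = as.vector(xm %*% hi))
}

.idwt_step <- function(a, d, lo, hi) {
  n2 <- length(a)
  n <- 2L * n2
  k <- length(lo)
  x <- numeric(n)
  for (i in seq_len(n2)) {
    pos <- (2L * (i - 1L) + seq_len(k) - 1L) %% n + 1L
    x[pos] <- x[pos] + a[i] * lo + d[i] * hi
  }
  x
}

#' Wavelet denoising by universal soft thresholding
#'
#' Decomposes the signal with a periodized orthonormal discrete wavelet
#' transform (sym4 filter bank) to the requested number of levels, applies
#' the universal soft threshold `sigma * sqrt(2 log n)` (with `sigma`
#' estimated by the median absolute deviation of the finest detail level)
#' to all detail coefficients, and reconstructs. Orthonormality guarantees
#' the output energy never exceeds the input energy.
#'
#' @param y numeric vector; `length(y)` must be divisible by `2^levels`.
#' @param levels decomposition depth (the selection harness scans 5-19;
#'   levels infeasible for the signal length raise an error).
#' @return denoised vector, same length as `y`.
#' @export
waveletDenoise <- function(y, levels = 5L) {
  levels <- as.integer(levels)
  n <- length(y)
  if (levels < 1L || n %% (2L^levels) != 0L || n %/% (2L^levels) < 1L)
    stop(sprintf(
      "waveletDenoise: %d decomposition levels infeasible for length %d",
      levels, n), call. = FALSE)
  lo <- .sym4_lo
  hi <- rev(lo) * (-1)^(seq_along(lo))      # quadrature mirror filter
  a <- y
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    s <- .dwt_step(a, lo, hi)
    a <- s$a
    details[[j]] <- s$d
  }
  sigma <- mad(details[[1L]], center = 0)
  thr <- sigma * sqrt(2 * log(max(n, 2L)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (j in seq_len(levels)) details[[j]] <- soft(details[[j]])
  for (j in rev(seq_len(levels)))
    a <- .idwt_step(a, details[[j]], lo, hi)
  a
}

#' Signal-to-noise ratio of a denoised signal, in dB
#'
#' `10 log10( sum(denoised^2) / sum((raw - denoised)^2) )`: the power of
#' the retained signal over the power of the removed residual. Used to
#' rank denoisers when no ground truth is available.
#'
#' @param raw,denoised equal-length numeric vectors; `denoised` must not
#'   be identically zero.
#' @return SNR in decibels; `Inf` when the residual is exactly zero.
#' @export
snrDb <- function(raw, denoised) {
  if (length(raw) != length(denoised))
    stop("snrDb: inputs must have equal length", call. = FALSE)
  if (all(denoised == 0))
    stop("snrDb: denoised signal is identically zero", call. = FALSE)
  res <- sum((raw - denoised)^2)
  if (res == 0) return(Inf)
  10 * log10(sum(denoised^2) / res)
}

#' Denoiser selection harness
#'
#' Applies Savitzky-Golay filters (orders 3, 5, 7 at a given window) and
#' wavelet denoising (a range of decomposition levels) to a spectrum and
#' tabulates the resulting SNR, the criterion used to pick the production
#' denoiser.
#'
#' @param y a raw intensity vector.
#' @param sgOrders polynomial orders to try.
#' @param sgWindow SG window length; orders that require a longer window
#'   use the smallest odd window exceeding the order.
#' @param wtLevels wavelet decomposition depths to try; infeasible depths
#'   are reported as `NA`.
#' @return `data.frame` with columns `method`, `parameter`, `snr_db`.
#' @export
denoiserComparison <- function(y, sgOrders = c(3, 5, 7), sgWindow = 7,
                               wtLevels = 5:19) {
  rows <- list()
  for (p in sgOrders) {
    w <- max(sgWindow, p + 1L + p %% 2L)   # smallest odd window > order
    sm <- sgSmooth(y, order = p, window = w)
    rows[[length(rows) + 1L]] <- data.frame(
      method = "sg", parameter = sprintf("order=%d,window=%d", p, w),
      snr_db = snrDb(y, sm))
  }
  for (J in wtLevels) {
    s <- tryCatch(snrDb(y, waveletDenoise(y, J)), error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      method = "wt", parameter = sprintf("levels=%d", J), snr_db = s)
  }
  do.call(rbind, rows)
}

# polynomial least-squares fit on x rescaled to [-1, 1] for conditioning
.polyfit <- function(x, y, degree) {
  u <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  X <- outer(u, 0:degree, `^`)
  fit <- lm.fit(X, y)
  as.vector(X %*% fit$coefficients)
}

#' Estimate a spectral baseline
#'
#' Three estimators of the slowly varying continuum under the peaks:
#' \describe{
#'   \item{`linear`}{a single straight-line least-squares fit (degree
#'     forced to 1).}
#'   \item{`polynomial`}{a single polynomial least-squares fit of the
#'     stated degree.}
#'   \item{`iterative_polynomial`}{ModPoly-style iteration: fit a
#'     degree-`degree` polynomial to the working signal, clamp the working
#'     signal to the pointwise minimum of itself and the fit, and repeat
#'     until the fitted baseline changes by less than `tol` (relative
#'     max-abs) or `maxIter` is reached. Peaks are progressively excluded
#'     from the estimate, so the fit converges onto the continuum.}
#' }
#'
#' @param y intensity vector.
#' @param x wavelength vector, strictly increasing, same length as `y`.
#' @param method one of `"linear"`, `"polynomial"`,
#'   `"iterative_polynomial"`.
#' @param degree polynomial degree (ignored for `"linear"`).
#' @param maxIter,tol iteration controls for the iterative method.
#' @return list with `baseline` (fitted vector), `r_squared` (coefficient
#'   of determination of the fit against its target signal: `y` for the
#'   single-fit methods, the final clamped working signal for the
#'   iterative method), and `n_iter`.
#' @export
fitBaseline <- function(y, x = seq_along(y),
                        method = c("iterative_polynomial", "polynomial",
                                   "linear"),
                        degree = 4, maxIter = 50, tol = 1e-4) {
  method <- match.arg(method)
  degree <- as.integer(degree)
  if (length(x) != length(y))
    stop("fitBaseline: x and y must have equal length", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("fitBaseline: x must be strictly increasing", call. = FALSE)
  if (method == "linear") degree <- 1L
  if (length(y) < degree + 2L)
    stop("fitBaseline: too few points for the requested degree", call. = FALSE)

  r2 <- function(target, fit) {
    ss_res <- sum((target - fit)^2)
    ss_tot <- sum((target - mean(target))^2)
    if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
    1 - ss_res / ss_tot
  }

  if (method %in% c("linear", "polynomial")) {
    b <- .polyfit(x, y, degree)
    return(list(baseline = b, r_squared = r2(y, b), n_iter = 1L))
  }
  work <- y
  b_prev <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    b <- .polyfit(x, work, degree)
    if (!is.null(b_prev)) {
      denom <- max(abs(b_prev))
      if (denom == 0) denom <- 1
      if (max(abs(b - b_prev)) / denom < tol) break
    }
    if (iter >= maxIter) break
    work <- pmin(work, b)
    b_prev <- b
  }
  list(baseline = b, r_squared = r2(work, b), n_iter = iter)
}

#' Subtract a baseline, flooring at zero
#'
#' @param y intensity vector.
#' @param baseline fitted baseline, same length.
#' @return `pmax(y - baseline, 0)` — detector counts are nonnegative.
#' @export
correctBaseline <- function(y, baseline) {
  if (length(y) != length(baseline))
    stop("correctBaseline: inputs must have equal length", call. = FALSE)
  pmax(y - baseline, 0)
}

#' Build a preprocessing configuration
#'
#' @param sgOrder,sgWindow Savitzky-Golay order and odd window (defaults
#'   5 and 7, the highest-SNR setting of the selection harness).
#' @param baselineMethod `"iterative_polynomial"` (default),
#'   `"polynomial"`, `"linear"`, or `"none"` to skip correction.
#' @param baselineDegree polynomial degree for the baseline fit.
#' @param baselineMaxIter,baselineTol iteration controls.
#' @param normalize apply per-spectrum min-max normalization first.
#' @param stages stage order; default `normalize`, `sg`, `baseline`.
#' @return a [PreprocessConfig-class]
#' @export
preprocessConfig <- function(sgOrder = 5L, sgWindow = 7L,
                             baselineMethod = "iterative_polynomial",
                             baselineDegree = 4L, baselineMaxIter = 50L,
                             baselineTol = 1e-4, normalize = TRUE,
                             stages = c("normalize", "sg", "baseline")) {
  new("PreprocessConfig", sgOrder = as.integer(sgOrder),
      sgWindow = as.integer(sgWindow),
      baselineMethod = baselineMethod,
      baselineDegree = as.integer(baselineDegree),
      baselineMaxIter = as.integer(baselineMaxIter),
      baselineTol = as.numeric(baselineTol),
      normalize = isTRUE(normalize), stages = stages)
}

#' Preprocess every spectrum of a dataset
#'
#' Applies, per spectrum and in the configured stage order: min-max
#' normalization, Savitzky-Golay smoothing, and baseline correction
#' (fit then subtract, floored at zero). Labels, grid and metadata are
#' preserved; the operation is deterministic.
#'
#' @param ds a [SpectralSet-class]
#' @param cfg a [PreprocessConfig-class]
#' @return a preprocessed [SpectralSet-class] of identical shape.
#' @export
preprocessSpectra <- function(ds, cfg = preprocessConfig()) {
  stopifnot(is(ds, "SpectralSet"), is(cfg, "PreprocessConfig"))
  validObject(cfg)
  wl <- wavelengths(ds)
  mat <- intensities(ds)
  filt <- sgCoefficients(cfg@sgOrder, cfg@sgWindow)
  stages <- cfg@stages
  if (!cfg@normalize) stages <- setdiff(stages, "normalize")
  if (cfg@baselineMethod == "none") stages <- setdiff(stages, "baseline")
  out <- mat
  for (i in seq_len(ncol(mat))) {
    y <- mat[, i]
    for (st in stages) {
      y <- switch(st,
        normalize = minMaxNormalize(y),
        sg = sgSmooth(y, filt),
        baseline = {
          fb <- fitBaseline(y, wl, method = cfg@baselineMethod,
                            degree = cfg@baselineDegree,
                            maxIter = cfg@baselineMaxIter,
                            tol = cfg@baselineTol)
          correctBaseline(y, fb$baseline)
        })
    }
    out[, i] <- y
  }
  res <- ds
  SummarizedExperiment::assay(res, "intensity") <- out
  res
}
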