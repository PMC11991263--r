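test_that("min-max normalization maps to [0, 1] and preserves order", {
  expect_equal(minMaxNormalize(c(2, 4, 6)), c(0, 0.5, 1))
  y <- c(0, 0.3, 1, 0.7)
  expect_equal(minMaxNormalize(y), y)
  set.seed(4)
  r <- rnorm(200)
  n <- minMaxNormalize(r)
  expect_equal(range(n), c(0, 1))
  expect_equal(cor(r, n, method = "spearman"), 1)
  expect_equal(n, (r - min(r)) / (max(r) - min(r)))   # direct formula
  expect_error(minMaxNormalize(rep(3, 5)), "degenerate")
  expect_error(minMaxNormalize(1), "length")
})

test_that("SG coefficients solve the central least-squares problem", {
  expect_equal(sgCoefficients(0, 3)@coefficients, rep(1 / 3, 3))
  for (order in 0:6) {
    for (window in seq(3, 11, by = 2)) {
      if (window <= order) next
      f <- sgCoefficients(order, window)
      w <- f@coefficients
      expect_equal(w, sgOracleWeights(order, window), tolerance = 1e-12)
      expect_equal(sum(w), 1, tolerance = 1e-10)
      expect_equal(w, rev(w), tolerance = 1e-10)   # symmetry
    }
  }
  expect_error(sgCoefficients(2, 4), "odd")
  expect_error(sgCoefficients(5, 5), "exceed")
})

test_that("SG filtering reproduces polynomials exactly, edges included", {
  x <- seq(0, 1, length.out = 50)
  y <- 3 * x^2 - x + 2
  sm <- sgSmooth(y, order = 3, window = 7)
  expect_lt(max(abs(sm - y)) / max(abs(y)), 1e-9)
  expect_equal(sgSmooth(rep(5, 20), order = 2, window = 5), rep(5, 20))
  # order-5 window-7: the production setting
  y5 <- 2 - x + x^3 - 0.5 * x^5
  expect_lt(max(abs(sgSmooth(y5, order = 5, window = 7) - y5)), 1e-9)
  expect_error(sgSmooth(1:3, order = 2, window = 5), "shorter")
})

test_that("SG filtering agrees with the signal package on interior points", {
  set.seed(7)
  y <- cumsum(rnorm(100))
  ours <- sgSmooth(y, order = 3, window = 9)
  ref <- as.vector(signal::sgolayfilt(y, p = 3, n = 9))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("SG smoothing reduces noise on a smooth signal", {
  set.seed(12)
  x <- seq(0, 4 * pi, length.out = 400)
  clean <- sin(x)
  noisy <- clean + rnorm(400, 0, 0.2)
  sm <- sgSmooth(noisy, order = 3, window = 11)
  expect_lt(var(sm - clean), var(noisy - clean))
})

test_that("wavelet denoising behaves on clean, polynomial and noisy input", {
  expect_equal(waveletDenoise(numeric(64), 5), numeric(64))
  x <- seq(0, 1, length.out = 256)
  poly <- 1 + 2 * x - x^2
  wd <- waveletDenoise(poly, 5)
  expect_lt(max(abs(wd - poly)) / max(abs(poly)), 1e-3)
  set.seed(3)
  clean <- sin(seq(0, 8 * pi, length.out = 512))
  noisy <- clean + rnorm(512, 0, 0.15)
  den <- waveletDenoise(noisy, 6)
  expect_gt(snrDb(noisy, den), 10)
  expect_lt(sum((den - clean)^2), sum((noisy - clean)^2))
  expect_lte(sum(den^2), sum(noisy^2) + 1e-9)   # energy not increased
  expect_error(waveletDenoise(rnorm(100), 5), "infeasible")
})

test_that("SNR follows the power-ratio definition", {
  s <- rep(10, 4)                     # signal power 400
  raw <- s + c(2, 0, 0, 0)            # residual power 4 -> ratio 100
  expect_equal(snrDb(raw, s), 20)
  expect_identical(snrDb(s, s), Inf)
  expect_error(snrDb(s, rep(0, 4)), "zero")
  expect_error(snrDb(1:3, 1:4), "equal length")
})

test_that("denoiser comparison harness tabulates SG and WT settings", {
  set.seed(5)
  y <- abs(rnorm(2048, 100, 5)) + 50 * exp(-(1:2048 - 800)^2 / 50)
  tab <- denoiserComparison(y)
  expect_named(tab, c("method", "parameter", "snr_db"))
  expect_equal(sum(tab$method == "sg"), 3L)
  expect_equal(sum(tab$method == "wt"), 15L)        # levels 5..19
  expect_true(all(is.na(tab$snr_db[tab$method == "wt"][8:15])))  # > 11 levels
  expect_true(all(is.finite(tab$snr_db[tab$method == "sg"])))
})

test_that("iterative polynomial baseline recovers a peak-free cubic", {
  x <- seq(370, 1100, length.out = 500)
  u <- (x - 370) / 730
  cubic <- 1200 - 1500 * u + 900 * u^2 - 300 * u^3
  fb <- fitBaseline(cubic, x, method = "iterative_polynomial", degree = 3)
  expect_lt(max(abs(fb$baseline - cubic)), 1e-8)
  expect_gte(fb$r_squared, 0.999)
  expect_lte(fb$n_iter, 50)
})

test_that("iterative baseline ignores peaks; linear fit is worse", {
  x <- seq(370, 1100, length.out = 1000)
  u <- (x - 370) / 730
  cubic <- 1200 - 1500 * u + 900 * u^2 - 300 * u^3
  centers <- c(450, 589, 656, 766, 950)
  peaks <- rowSums(vapply(centers, function(c0)
    3000 * exp(-(x - c0)^2 / (2 * 1.5^2)), numeric(length(x))))
  y <- cubic + peaks
  it <- fitBaseline(y, x, method = "iterative_polynomial", degree = 3,
                    maxIter = 100, tol = 1e-6)
  free <- rowSums(vapply(centers, function(c0) abs(x - c0) < 10,
                         logical(length(x)))) == 0
  relErr <- abs(it$baseline[free] - cubic[free]) / abs(cubic[free])
  expect_lt(max(relErr), 0.02)
  lin <- fitBaseline(y, x, method = "linear")
  expect_lt(lin$r_squared, it$r_squared)
  # the iterative estimate sits below the single polynomial fit at peaks
  single <- fitBaseline(y, x, method = "polynomial", degree = 3)
  on_peak <- which.min(abs(x - 656))
  expect_lt(it$baseline[on_peak], single$baseline[on_peak])
  expect_error(fitBaseline(y, rev(x)), "increasing")
})

test_that("baseline correction subtracts and floors at zero", {
  y <- c(3, 5, 2)
  expect_equal(correctBaseline(y, y), c(0, 0, 0))
  base <- rep(2, 100)
  peak <- base + 10 * exp(-(1:100 - 50)^2 / 8)
  corr <- correctBaseline(peak, base)
  expect_equal(max(corr), 10, tolerance = 1e-6)
  expect_equal(corr[1:30], rep(0, 30), tolerance = 1e-6)
  expect_error(correctBaseline(1:3, 1:4), "equal length")
})

test_that("preprocessing pipeline composes stages and preserves labels", {
  ds <- fxSmallSet()
  # empty stage list leaves data untouched
  idcfg <- preprocessConfig(stages = character())
  expect_identical(intensities(preprocessSpectra(ds, idcfg)),
                   intensities(ds))
  pp <- preprocessSpectra(ds, preprocessConfig())
  expect_equal(dim(pp), dim(ds))
  expect_identical(classLabels(pp), classLabels(ds))
  expect_identical(wavelengths(pp), wavelengths(ds))
  m <- intensities(pp)
  expect_gte(min(m), 0)
  expect_lte(max(m), 1 + 1e-6)
  # deterministic
  pp2 <- preprocessSpectra(ds, preprocessConfig())
  expect_identical(intensities(pp), intensities(pp2))
})
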