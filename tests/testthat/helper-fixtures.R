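# Shared fixtures, built lazily once per test run.

.fx <- new.env()

# a small two-class dataset with one strongly discriminative line
fxSmallSet <- function() {
  if (is.null(.fx$small)) {
    cfg <- singleLineConfig(seed = 11, tabletsPerClass = 4L,
                            shotsPerTablet = 10L)
    .fx$small <- generateSpectra(cfg)
  }
  .fx$small
}

# the full study-sized dataset (2 x 20 x 50 = 2000 spectra)
fxDefaultSet <- function() {
  if (is.null(.fx$full)) .fx$full <- generateSpectra(defaultSynthConfig(seed = 1))
  .fx$full
}

# preprocessed full dataset (shared by split / training checks)
fxDefaultPreprocessed <- function() {
  if (is.null(.fx$full_pp)) .fx$full_pp <- preprocessSpectra(fxDefaultSet())
  .fx$full_pp
}

# brute-force Savitzky-Golay oracle: central least-squares weights from an
# explicit per-window polynomial fit (normal equations), independent of
# the implementation under test
sgOracleWeights <- function(order, window) {
  m <- (window - 1L) %/% 2L
  X <- outer(seq(-m, m), 0:order, `^`)
  w <- numeric(window)
  for (i in seq_len(window)) {
    y <- numeric(window); y[i] <- 1
    beta <- solve(crossprod(X), crossprod(X, y))
    w[i] <- beta[1L]   # fitted value at the window center (position 0)
  }
  w
}

# hand-rolled squeeze-excitation evaluation for oracle comparison
seOracle <- function(x, W1, W2, b1 = 0, b2 = 0) {
  s <- rowMeans(x)
  a1 <- pmax(as.vector(W1 %*% s) + b1, 0)
  z <- 1 / (1 + exp(-(as.vector(W2 %*% a1) + b2)))
  x * z
}
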