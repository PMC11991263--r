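test_that("default configuration matches the study design", {
  cfg <- defaultSynthConfig(seed = 5)
  expect_equal(cfg@nPoints, 2048L)
  expect_equal(c(cfg@gridStart, cfg@gridEnd), c(370, 1100))
  expect_equal(cfg@nClasses, 2L)
  expect_equal(cfg@tabletsPerClass, 20L)
  expect_equal(cfg@shotsPerTablet, 50L)
  expect_true(all(c(616.22, 589.14, 656.26, 766.49) %in%
                    cfg@lines$center_nm))
  expect_gte(nrow(cfg@lines), 12L)   # 4 named + >= 8 filler lines
  # classes share multipliers everywhere except the discriminative subset
  disc <- which(cfg@classMultipliers[1, ] != cfg@classMultipliers[2, ])
  expect_true(length(disc) >= 1 && length(disc) < nrow(cfg@lines))
  expect_true(any(cfg@baselineCoeffs != 0))
  expect_gt(cfg@noiseSd, 0)
})

test_that("generator produces the full replicate design", {
  ds <- fxDefaultSet()
  expect_equal(ncol(ds), 2000L)
  expect_equal(nrow(ds), 2048L)
  expect_equal(unname(table(classLabels(ds))), c(1000L, 1000L),
               ignore_attr = TRUE)
  expect_equal(length(unique(tabletIds(ds))), 40L)
  expect_equal(unname(table(table(tabletIds(ds)))), 40L, ignore_attr = TRUE)
  expect_true(all(intensities(ds) >= 0))
})

test_that("noise-free single-line spectra peak at the line center", {
  lines <- data.frame(element = "K", center_nm = 766.49,
                      base_intensity = 1000, width_nm = 0.7)
  cfg <- synthConfig(lines = lines, classMultipliers = matrix(1, 2, 1),
                     baselineCoeffs = 0, noiseSd = 0, tabletJitterSd = 0,
                     tabletsPerClass = 2L, shotsPerTablet = 2L, seed = 1)
  ds <- generateSpectra(cfg)
  wl <- wavelengths(ds)
  target <- which.min(abs(wl - 766.49))
  peaks <- apply(intensities(ds), 2, which.max)
  expect_true(all(peaks == target))
})

test_that("generation is deterministic under the seed", {
  cfg <- singleLineConfig(seed = 42, tabletsPerClass = 2L, shotsPerTablet = 3L)
  a <- generateSpectra(cfg)
  b <- generateSpectra(cfg)
  expect_identical(intensities(a), intensities(b))
  cfg2 <- singleLineConfig(seed = 43, tabletsPerClass = 2L, shotsPerTablet = 3L)
  expect_false(identical(intensities(a),
                         intensities(generateSpectra(cfg2))))
})

test_that("class-conditional means differ only near discriminative lines", {
  cfg <- defaultSynthConfig(seed = 2)
  cfg@noiseSd <- 0
  cfg@tabletJitterSd <- 0
  cfg@tabletsPerClass <- 2L
  cfg@shotsPerTablet <- 2L
  ds <- generateSpectra(cfg)
  wl <- wavelengths(ds)
  cl <- classLabels(ds)
  m1 <- rowMeans(intensities(ds)[, cl == levels(cl)[1], drop = FALSE])
  m2 <- rowMeans(intensities(ds)[, cl == levels(cl)[2], drop = FALSE])
  d <- abs(m1 - m2)
  disc <- which(cfg@classMultipliers[1, ] != cfg@classMultipliers[2, ])
  nearDisc <- rowSums(vapply(disc, function(j)
    abs(wl - cfg@lines$center_nm[j]) < 8 * cfg@lines$width_nm[j],
    logical(length(wl)))) > 0
  expect_gt(max(d[nearDisc]), 0)
  expect_lt(max(d[!nearDisc]), 1e-8 * max(d))
})

test_that("invalid configurations raise labeled errors", {
  lines <- data.frame(element = "X", center_nm = 500,
                      base_intensity = 1, width_nm = 0.5)
  expect_error(synthConfig(lines = lines,
                           classMultipliers = matrix(1, 3, 1),
                           nClasses = 2L), "classMultipliers")
  expect_error(synthConfig(lines = data.frame(element = "X",
                                              center_nm = 2000,
                                              base_intensity = 1,
                                              width_nm = 0.5),
                           classMultipliers = matrix(1, 2, 1)),
               "within the grid")
})
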