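test_that("saliency maps have the right shape and range", {
  ds <- fxSmallSet()
  pp <- preprocessSpectra(ds)
  m <- buildModel(netConfig(inputLength = nrow(pp)), seed = 2)
  sm <- gradCam1d(m, pp[, 1])
  expect_s4_class(sm, "SaliencyMap")
  expect_length(relevance(sm), nrow(pp))
  expect_equal(wavelengths(sm), wavelengths(pp))
  expect_gte(min(relevance(sm)), 0)
  expect_lte(max(relevance(sm)), 1)
  # both taps and both streams are addressable
  for (tl in c("rsm", "multiscale"))
    for (st in c("raw", "diff"))
      expect_s4_class(gradCam1d(m, pp[, 2], targetLayer = tl, stream = st),
                      "SaliencyMap")
  expect_error(gradCam1d(m, pp[, 1], classIndex = 9), "out of range")
  expect_error(gradCam1d(m, pp[, 1:2]), "single")
})

test_that("zero gradients yield an identically zero map", {
  ds <- fxSmallSet()
  pp <- preprocessSpectra(ds)
  m <- buildModel(netConfig(inputLength = nrow(pp)), seed = 2)
  last <- m$params$mlp[[length(m$params$mlp)]]
  last$W <- 0 * last$W
  last$b <- 0 * last$b
  sm <- gradCam1d(m, pp[, 1], classIndex = 1)
  expect_equal(relevance(sm), numeric(nrow(pp)) + 0)
})

test_that("sequential baseline models refuse saliency probes", {
  m <- buildClassicCnn("lenet", 256L, 2L)
  expect_error(gradCam1d(m, rnorm(256)), "target layer")
})

test_that("a trained model concentrates saliency at the marker region", {
  ds <- fxSmallSet()        # marked class: O 777.19 nm enhanced
  pp <- preprocessSpectra(ds)
  parts <- splitDataset(pp, c(0.6, 0.2, 0.2), seed = 1)
  m <- buildModel(netConfig(inputLength = nrow(pp)), seed = 1)
  trainModel(m, parts$train, parts$val,
             trainConfig(learningRate = 0.02, epochs = 8L,
                         batchSize = 16L, seed = 1))
  ev <- evaluateModel(m, parts$test)
  expect_gte(accuracy(ev), 0.9)
  wl <- wavelengths(pp)
  target <- which.min(abs(wl - markerLines(singleLineConfig())[2L]))
  pred <- predictClasses(m, parts$test)
  ok <- which(pred == classLabels(parts$test))
  markedIdx <- match("marked", spectrumClasses(pp))
  # marked-class saliency concentrates in the marker neighbourhood
  # (+-15 grid points, ~5 nm: the reliable localization scale of
  # gradient-weighted maps at this feature-map stride)
  d <- vapply(head(ok, 20), function(i) {
    sm <- gradCam1d(m, parts$test[, i], classIndex = markedIdx)
    abs(which.max(relevance(sm)) - target)
  }, 0)
  expect_lte(median(d), 15)
  # an untrained model does not show the same attribution profile
  m0 <- buildModel(netConfig(inputLength = nrow(pp)), seed = 9)
  sm_tr <- relevance(gradCam1d(m, parts$test[, ok[1]]))
  sm_un <- relevance(gradCam1d(m0, parts$test[, ok[1]]))
  expect_false(isTRUE(all.equal(sm_tr, sm_un)))
})

test_that("saliency maps serialize to delimited text", {
  ds <- fxSmallSet()
  m <- buildModel(netConfig(inputLength = nrow(ds)), seed = 1)
  sm <- gradCam1d(m, preprocessSpectra(ds)[, 1])
  path <- file.path(tempdir(), "sal.csv")
  writeSaliency(sm, path)
  back <- read.csv(path)
  expect_equal(back$relevance, relevance(sm), tolerance = 1e-12)
})
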