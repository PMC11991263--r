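test_that("backward difference matches its definition", {
  expect_equal(backwardDifference(rep(7, 6), 1), rep(0, 6))
  expect_equal(backwardDifference(c(0, 2, 4, 6), 1), c(0, 2, 2, 2))
  set.seed(8)
  y <- rnorm(30)
  h <- 2L
  manual <- numeric(30)
  for (k in (h + 1):30) manual[k] <- (y[k] - y[k - h]) / h
  expect_equal(backwardDifference(y, h), manual)
  expect_error(backwardDifference(1:5, 0), "h")
  expect_error(backwardDifference(1:5, 5), "h")
})

test_that("squeeze-excitation matches a hand-rolled evaluation", {
  set.seed(21)
  x <- matrix(rnorm(4 * 8), 4, 8)
  W1 <- matrix(0, 2, 4); W2 <- matrix(0, 4, 2)
  r <- seForward(x, W1, W2)
  expect_equal(r$weights, rep(0.5, 4))
  expect_equal(r$out, x * 0.5)
  W1 <- matrix(rnorm(8), 2, 4); W2 <- matrix(rnorm(8), 4, 2)
  b1 <- rnorm(2); b2 <- rnorm(4)
  r <- seForward(x, W1, W2, b1, b2)
  expect_true(all(r$weights > 0 & r$weights < 1))
  expect_equal(r$out, seOracle(x, W1, W2, b1, b2), tolerance = 1e-12)
})

test_that("residual blocks satisfy y = F(x) + shortcut(x)", {
  set.seed(5)
  x <- matrix(rnorm(4 * 8), 4, 8)
  # F = 0 (all weights zero), identity shortcut -> output == input
  blk <- newResBlock(4, seed = 1)
  for (p in LIBSnet:::.collect_params(blk))
    for (nm in p$pnames) assign(nm, 0 * get(nm, p), p)
  expect_equal(residualForward(x, blk), x, tolerance = 1e-12)
  # Res_Down with zero main path -> output == 1x1 convolution of x
  dn <- newResBlock(4, 6, stride = 1L, seed = 2)
  for (nm2 in c("conv1", "conv2", "bn1", "bn2", "se1", "se2"))
    for (nm in dn[[nm2]]$pnames)
      assign(nm, 0 * get(nm, dn[[nm2]]), dn[[nm2]])
  manual <- dn$sc$W %*% x + dn$sc$b
  expect_equal(residualForward(x, dn), unname(manual), tolerance = 1e-12,
               ignore_attr = TRUE)
  # random block equals the independent interpreter recomputation
  rb <- newResBlock(4, seed = 3)
  xa <- array(x, c(4, 8, 1))
  ref <- LIBSnet:::.resblock_fwd_r(rb, xa, training = FALSE)$presum
  expect_equal(residualForward(x, rb), matrix(ref, 4), tolerance = 1e-10)
})

test_that("compiled residual block agrees with the interpreter reference", {
  set.seed(31)
  ns <- asNamespace("LIBSnet")
  x <- array(rnorm(6 * 16 * 4), c(6, 16, 4))
  bd <- ns$.new_resdown(6L, 8L, 2L, 2L)
  for (training in c(TRUE, FALSE)) {
    a <- ns$.resblock_fwd(bd, x, training, stride = 2L, keep = TRUE)
    b <- ns$.resblock_fwd_r(bd, x, training, stride = 2L)
    expect_equal(a$out, b$out, tolerance = 1e-12)
    gy <- array(rnorm(length(a$out)), dim(a$out))
    gx_cpp <- ns$.resblock_bwd(bd, a$cache, gy)
    ns$.zero_grads(ns$.collect_params(bd))
    gx_ref <- ns$.resblock_bwd_r(bd, b$cache, gy)
    ns$.zero_grads(ns$.collect_params(bd))
    expect_equal(gx_cpp, gx_ref, tolerance = 1e-10)
    LIBSnet:::cpp_resblock_clear()
  }
})

test_that("model construction honours sharing, ablation and shapes", {
  cfg <- netConfig(inputLength = 2048L)
  m <- buildModel(cfg, seed = 0)
  # shared streams reference the same parameter objects
  expect_identical(m$params$stream1$mergeConv, m$params$stream2$mergeConv)
  m$params$stream1$mergeConv$W[1, 1] <- 99
  expect_equal(m$params$stream2$mergeConv$W[1, 1], 99)
  # parameter count: shared dual-stream == unshared minus one stream
  m2 <- buildModel(netConfig(shareStreamWeights = FALSE), seed = 0)
  streamCount <- sum(vapply(LIBSnet:::.collect_params(m$params$stream1),
    function(p) sum(vapply(p$pnames, function(nm) length(get(nm, p)), 0)), 0))
  expect_equal(LIBSnet:::.n_params(m2) - LIBSnet:::.n_params(m), streamCount)
  # ablation arms build
  base <- buildModel(netConfig(useBackwardDifference = FALSE,
                               useMultiscale = FALSE), seed = 0)
  expect_null(base$params$stream2)
  expect_false(is.null(base$params$stream1$stem))
  # forward-pass shape contract on a batch of 6 spectra of length 2048
  X <- array(runif(2048 * 6), c(1, 2048, 6))
  lg <- LIBSnet:::.net_fwd(m, X, training = FALSE, keep = FALSE)$logits
  expect_equal(dim(lg), c(2L, 6L))
  expect_error(buildModel(netConfig(branchChannels = 3L, seReduction = 4L)),
               "seReduction")
})

test_that("dataset splitting reproduces the protocol arithmetic", {
  ds <- fxDefaultSet()
  p3 <- splitDataset(ds, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(vapply(p3, ncol, 0L),
               c(train = 1200L, val = 400L, test = 400L))
  p2 <- splitDataset(ds, c(0.7, 0.3), seed = 1)
  expect_equal(vapply(p2, ncol, 0L), c(train = 1400L, test = 600L))
  # stratification: class balance preserved exactly
  expect_equal(unname(table(classLabels(p3$test))), c(200L, 200L),
               ignore_attr = TRUE)
  # tiny case: N = 10 at 6:2:2 -> 6/2/2
  small <- SpectralSet(matrix(runif(50), 5), 1:5,
                       classes = rep(c("A", "B"), each = 5))
  ps <- splitDataset(small, c(0.6, 0.2, 0.2), seed = 0)
  expect_equal(vapply(ps, ncol, 0L), c(train = 6L, val = 2L, test = 2L))
  # determinism
  q <- splitDataset(ds, c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(sampleIds(q$test), sampleIds(p3$test))
  expect_error(splitDataset(small[, 1:3], c(0.6, 0.2, 0.2)), "fewer")
})

test_that("group-aware splitting keeps tablets intact", {
  ds <- fxDefaultSet()
  p <- splitDataset(ds, c(0.6, 0.2, 0.2), seed = 3, groupAware = TRUE)
  tabs <- lapply(p, tabletIds)
  expect_length(intersect(tabs$train, tabs$val), 0L)
  expect_length(intersect(tabs$train, tabs$test), 0L)
  expect_length(intersect(tabs$val, tabs$test), 0L)
  # 20 tablets x 50 shots per class divide exactly at 6:2:2
  expect_equal(vapply(p, ncol, 0L),
               c(train = 1200L, val = 400L, test = 400L))
})

test_that("zero learning rate leaves weights unchanged", {
  ds <- fxSmallSet()
  pp <- preprocessSpectra(ds)
  m <- buildModel(netConfig(inputLength = nrow(pp)), seed = 1)
  w0 <- m$params$mlp[[1]]$W
  trainModel(m, pp, tcfg = trainConfig(learningRate = 0, epochs = 1L,
                                       batchSize = 16L, seed = 1))
  expect_identical(m$params$mlp[[1]]$W, w0)
})

test_that("training separates a strongly discriminative synthetic task", {
  ds <- fxSmallSet()
  pp <- preprocessSpectra(ds)
  parts <- splitDataset(pp, c(0.6, 0.2, 0.2), seed = 0)
  m <- buildModel(netConfig(inputLength = nrow(pp)), seed = 0)
  tr <- trainModel(m, parts$train, parts$val,
                   trainConfig(learningRate = 0.02, epochs = 6L,
                               batchSize = 16L, seed = 0))
  expect_gte(tail(tr$traces$train_acc, 1), 0.99)
  ev <- evaluateModel(m, parts$test, tr$traces)
  expect_s4_class(ev, "ClassifierEval")
  expect_equal(sum(confusionCounts(ev)), ncol(parts$test))
  expect_gte(accuracy(ev), 0.9)
  # evaluation is deterministic (dropout off, running statistics)
  expect_equal(accuracy(evaluateModel(m, parts$test)), accuracy(ev))
  expect_error(evaluateModel(m, parts$test[, 0]), "empty")
})

test_that("divergent training raises a labeled error naming the epoch", {
  ds <- fxSmallSet()
  pp <- preprocessSpectra(ds)
  m <- buildModel(netConfig(inputLength = nrow(pp)), seed = 1)
  expect_error(
    trainModel(m, pp, tcfg = trainConfig(learningRate = 1e9, epochs = 3L,
                                         batchSize = 16L, seed = 1)),
    "epoch")
})
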