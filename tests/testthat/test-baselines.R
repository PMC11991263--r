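test_that("accuracy worked examples reproduce the protocol arithmetic", {
  expect_equal(accuracyFromCounts(c(223, 230), 600), 75.5)
  expect_equal(accuracyFromCounts(c(247, 231), 600), 79.7)
  expect_equal(accuracyFromCounts(c(269, 251), 600), 86.7)
  expect_equal(accuracyFromCounts(c(136, 136), 400), 68.0)
  expect_equal(accuracyFromCounts(c(144, 156), 400), 75.0)
  expect_equal(accuracyFromCounts(c(151, 139), 400), 72.5)
  expect_equal(accuracyFromCounts(c(188, 192), 400), 95.0)
  expect_equal(accuracyFromCounts(c(0, 0), 600), 0.0)
  expect_equal(accuracyFromCounts(c(100), 100), 100.0)
  expect_error(accuracyFromCounts(c(10, 10), 0), "positive")
  expect_error(accuracyFromCounts(c(400, 300), 600), "exceed")
})

test_that("accuracyFromCounts agrees with ClassifierEval on any confusion", {
  set.seed(14)
  for (i in 1:10) {
    counts <- matrix(sample(0:50, 4, replace = TRUE), 2)
    ev <- new("ClassifierEval", counts = counts,
              accuracy = sum(diag(counts)) / sum(counts),
              traces = data.frame())
    expect_equal(accuracyFromCounts(diag(counts), sum(counts)),
                 round(100 * accuracy(ev), 1))
  }
})

test_that("classical ML protocol: split sizes, CV, and separability", {
  ds <- fxSmallSet()
  pp <- preprocessSpectra(ds)
  r <- runMl(pp, mlSpec("knn"), seed = 1)
  expect_equal(r$n_train, 56L)          # 0.7 of 80
  expect_equal(r$n_test, 24L)
  expect_s4_class(r$eval, "ClassifierEval")
  # the single-line task is strongly separable
  expect_gte(r$cv_accuracy, 0.95)
  expect_gte(accuracy(r$eval), 0.9)
  expect_error(runMl(pp, structure(list(method = "svm"), class = "MLSpec")),
               "unknown")
})

test_that("random forest beats a single decision tree on the same split", {
  ds <- fxDefaultSet()[, seq(1, 2000, by = 5)]    # 400-spectrum subsample
  pp <- preprocessSpectra(ds)
  rf <- runMl(pp, mlSpec("rf"), seed = 2)
  dt <- runMl(pp, mlSpec("dt"), seed = 2)
  expect_gte(accuracy(rf$eval), accuracy(dt$eval))
})

test_that("classic 1-D CNNs build with the documented structure", {
  for (nm in c("lenet", "alexnet_mod", "resnet18")) {
    m <- buildClassicCnn(nm, inputLength = 2048L, nClasses = 2L, seed = 0)
    X <- array(runif(2048 * 3), c(1, 2048, 3))
    lg <- LIBSnet:::.net_fwd(m, X, training = FALSE, keep = FALSE)$logits
    expect_equal(dim(lg), c(2L, 3L))
  }
  # modified AlexNet: batch-norm where the first two max-pools would be
  am <- buildClassicCnn("alexnet_mod", 2048L, 2L)
  ops <- vapply(am$layers, function(l) l$op, "")
  firstTwoStages <- ops[1:6]
  expect_equal(sum(firstTwoStages == "bn"), 2L)
  expect_equal(sum(firstTwoStages == "pool"), 0L)
  expect_equal(sum(ops == "pool"), 1L)   # later stage pooling retained
  # ResNet-18: 8 residual blocks
  rn <- buildClassicCnn("resnet18", 2048L, 2L)
  expect_equal(sum(vapply(rn$layers, function(l) l$op, "") == "resblock"), 8L)
  expect_error(buildClassicCnn("vgg"), "arg")
})

test_that("classic CNNs train end-to-end on a small dataset", {
  ds <- fxSmallSet()
  pp <- preprocessSpectra(ds)
  parts <- splitDataset(pp, c(0.7, 0.3), seed = 0)
  tcfg <- trainConfig(learningRate = 0.01, epochs = 2L, batchSize = 16L,
                      seed = 0)
  for (nm in c("lenet", "alexnet_mod", "resnet18")) {
    m <- buildClassicCnn(nm, inputLength = nrow(pp), nClasses = 2L, seed = 0)
    tr <- trainModel(m, parts$train, tcfg = tcfg)
    ev <- evaluateModel(m, parts$test)
    expect_true(is.finite(accuracy(ev)))
    expect_equal(sum(confusionCounts(ev)), ncol(parts$test))
  }
})

test_that("compareMethods produces one row per requested method", {
  ds <- fxSmallSet()
  pp <- preprocessSpectra(ds)
  tab <- compareMethods(pp, methods = c("knn", "dt"), seed = 1)
  expect_equal(tab$method, c("knn", "dt"))
  expect_true(all(tab$accuracy_pct >= 0 & tab$accuracy_pct <= 100))
  expect_true(all(!is.na(tab$cv_accuracy_pct)))
  expect_error(compareMethods(pp, methods = "mystery"), "unknown")
})
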