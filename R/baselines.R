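# ---------------------------------------------------------------------
# Comparison suite: classical ML classifiers (KNN / RF / DT) under the
# 7:3 + five-fold-CV protocol, and 1-D adaptations of LeNet, a modified
# AlexNet (batch-norm replacing the first two max-pools) and ResNet-18,
# built on the same engine as the main network.
# ---------------------------------------------------------------------

#' Specify a classical ML classifier
#'
#' @param method `"knn"`, `"rf"` or `"dt"`.
#' @param nNeighbors neighbours for KNN (default 5).
#' @param nEstimators trees for the random forest (default 100).
#' @param randomState RNG seed for RF/DT model fitting (default 42).
#' @param cvFolds cross-validation folds (default 5).
#' @return a list of class `MLSpec`.
#' @export
mlSpec <- function(method = c("knn", "rf", "dt"), nNeighbors = 5L,
                   nEstimators = 100L, randomState = 42L, cvFolds = 5L) {
  method <- match.arg(method)
  structure(list(method = method, nNeighbors = as.integer(nNeighbors),
                 nEstimators = as.integer(nEstimators),
                 randomState = as.integer(randomState),
                 cvFolds = as.integer(cvFolds)), class = "MLSpec")
}

.ml_fit_predict <- function(spec, Xtr, ytr, Xte) {
  switch(spec$method,
    knn = class::knn(Xtr, Xte, factor(ytr), k = spec$nNeighbors),
    rf = {
      set.seed(spec$randomState)
      fit <- randomForest::randomForest(Xtr, factor(ytr),
                                        ntree = spec$nEstimators)
      predict(fit, Xte)
    },
    dt = {
      set.seed(spec$randomState)
      df <- data.frame(y = factor(ytr), Xtr)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      nd <- data.frame(Xte)
      colnames(nd) <- colnames(df)[-1L]
      predict(fit, nd, type = "class")
    },
    stop(sprintf("unknown ML method '%s'", spec$method), call. = FALSE))
}

.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  set.seed(seed)
  for (lv in unique(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Run a classical ML classifier under the comparison protocol
#'
#' Splits the dataset 7:3 (stratified, deterministic under `seed`), fits
#' the classifier on the 70% portion using each spectrum's intensity
#' vector as features, reports the confusion counts on the held-out 30%,
#' and additionally reports the mean stratified five-fold
#' cross-validation accuracy on the training portion.
#'
#' @param ds a [SpectralSet-class] of (preprocessed) spectra.
#' @param spec an [mlSpec()].
#' @param ratios train/validation fractions (default `c(0.7, 0.3)`).
#' @param seed seed for the split and the CV folds.
#' @return list with `eval` (a [ClassifierEval-class] on the validation
#'   split), `cv_accuracy` (mean five-fold CV accuracy, fraction), and
#'   the partition sizes.
#' @export
runMl <- function(ds, spec, ratios = c(0.7, 0.3), seed = 0L) {
  stopifnot(is(ds, "SpectralSet"), inherits(spec, "MLSpec"))
  parts <- splitDataset(ds, ratios, seed = seed)
  Xtr <- t(intensities(parts$train)); ytr <- .labels_int(parts$train)
  Xte <- t(intensities(parts$test)); yte <- .labels_int(parts$test)
  pred <- as.integer(.ml_fit_predict(spec, Xtr, ytr, Xte))
  lv <- spectrumClasses(ds)
  counts <- table(factor(lv[yte], levels = lv), factor(lv[pred], levels = lv))
  counts <- matrix(as.integer(counts), nrow(counts),
                   dimnames = dimnames(counts))
  fold <- .stratified_folds(ytr, spec$cvFolds, seed)
  cvAcc <- vapply(seq_len(spec$cvFolds), function(f) {
    p <- as.integer(.ml_fit_predict(spec, Xtr[fold != f, , drop = FALSE],
                                    ytr[fold != f],
                                    Xtr[fold == f, , drop = FALSE]))
    mean(p == ytr[fold == f])
  }, 0)
  list(eval = new("ClassifierEval", counts = counts,
                  accuracy = sum(diag(counts)) / sum(counts),
                  traces = data.frame()),
       cv_accuracy = mean(cvAcc),
       n_train = nrow(Xtr), n_test = nrow(Xte))
}

#' Accuracy from per-class correct counts
#'
#' The worked-example arithmetic of the evaluation protocol:
#' `100 * sum(correct) / total`, reported to one decimal. Agrees with
#' [evaluateModel()]'s accuracy on any confusion matrix (same formula,
#' two code paths).
#'
#' @param correctPerClass integer vector of correctly classified counts
#'   per class.
#' @param total total number of evaluated spectra.
#' @return percentage rounded to one decimal.
#' @examples
#' accuracyFromCounts(c(223, 230), 600)   # 75.5
#' @export
accuracyFromCounts <- function(correctPerClass, total) {
  if (total <= 0) stop("accuracyFromCounts: total must be positive",
                       call. = FALSE)
  if (sum(correctPerClass) > total)
    stop("accuracyFromCounts: correct counts exceed total", call. = FALSE)
  round(100 * sum(correctPerClass) / total, 1L)
}

# ---- sequential-model engine -----------------------------------------

.seq_fwd <- function(model, x, training = FALSE, keep = training) {
  h <- x
  caches <- if (keep) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    r <- switch(ly$op,
      conv = .conv_fwd(h, ly$p, stride = ly$stride %||% 1L,
                       pad = ly$pad %||% ((ly$p$k - 1L) %/% 2L)),
      relu = .relu_fwd(h),
      bn = .bn_fwd(h, ly$p, training),
      pool = .pool_fwd(h, ly$w, ly$stride %||% ly$w),
      resblock = {
        rb <- .resblock_fwd(ly$p, h, training, stride = ly$p$stride %||% 1L,
                            keep = keep)
        list(out = rb$out, cache = rb$cache)
      },
      gap = .gap_fwd(h),
      flatten = {
        d <- dim(h)
        list(out = matrix(h, d[1L] * d[2L], d[3L]), cache = d)
      },
      dropout = .drop_fwd(h, if (isTRUE(model$nodrop)) 0 else ly$rate,
                          training),
      linear = .lin_fwd(h, ly$p),
      stop("unknown layer op"))
    h <- r$out
    if (keep) caches[[i]] <- r$cache
  }
  if (!keep) return(list(logits = h))
  list(logits = h, cache = caches)
}

.seq_bwd <- function(model, cache, glogits) {
  g <- glogits
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    g <- switch(ly$op,
      conv = .conv_bwd(ly$p, cache[[i]], g),
      relu = .relu_bwd(cache[[i]], g),
      bn = .bn_bwd(ly$p, cache[[i]], g),
      pool = .pool_bwd(cache[[i]], g),
      resblock = .resblock_bwd(ly$p, cache[[i]], g),
      gap = .gap_bwd(cache[[i]], g),
      flatten = array(g, cache[[i]]),
      dropout = .drop_bwd(cache[[i]], g),
      linear = .lin_bwd(ly$p, cache[[i]], g))
  }
  invisible(g)
}

.seq_out_len <- function(layers, L) {
  for (ly in layers) {
    L <- switch(ly$op,
      conv = (L + 2L * (ly$pad %||% ((ly$p$k - 1L) %/% 2L)) - ly$p$k) %/%
        (ly$stride %||% 1L) + 1L,
      pool = (L - ly$w) %/% (ly$stride %||% ly$w) + 1L,
      resblock = (L + 2L - 3L) %/% (ly$p$stride %||% 1L) + 1L,
      L)
  }
  L
}

#' Build a classical 1-D CNN
#'
#' 1-D adaptations of three stock architectures, with canonical layer
#' counts and kernel/stride settings chosen so the final feature length
#' stays >= 1 for the given input length:
#' \describe{
#'   \item{`lenet`}{two conv+max-pool stages and three fully connected
#'     layers.}
#'   \item{`alexnet_mod`}{five convolutional stages; the max-pools of the
#'     first two stages are replaced by 1-D batch normalization (the
#'     modification that avoids premature down-sampling of spectral
#'     features), the remaining structure unchanged.}
#'   \item{`resnet18`}{a stem convolution followed by four stages of two
#'     residual basic blocks (8 blocks, 18 weight layers with the stem
#'     and head), channel-doubling with strided 1x1-convolution
#'     shortcuts at stage boundaries, global average pooling and a linear
#'     head.}
#' }
#' `print()` on the returned model shows the architecture summary.
#'
#' @param name one of `"lenet"`, `"alexnet_mod"`, `"resnet18"`.
#' @param inputLength spectrum length.
#' @param nClasses number of classes.
#' @param seed RNG seed for weight initialization.
#' @return a `libsModel` usable with [trainModel()], [evaluateModel()].
#' @export
buildClassicCnn <- function(name = c("lenet", "alexnet_mod", "resnet18"),
                            inputLength = 2048L, nClasses = 2L, seed = 0L) {
  name <- match.arg(name)
  set.seed(seed)
  L <- as.integer(inputLength)
  layers <- list()
  add <- function(...) layers[[length(layers) + 1L]] <<- list(...)
  if (name == "lenet") {
    add(op = "conv", p = .param_conv(1L, 6L, 5L))
    add(op = "relu")
    add(op = "pool", w = 4L)
    add(op = "conv", p = .param_conv(6L, 16L, 5L))
    add(op = "relu")
    add(op = "pool", w = 4L)
    flatL <- .seq_out_len(layers, L) * 16L
    add(op = "flatten")
    add(op = "linear", p = .param_linear(flatL, 120L))
    add(op = "relu")
    add(op = "linear", p = .param_linear(120L, 84L))
    add(op = "relu")
    add(op = "linear", p = .param_linear(84L, nClasses))
  } else if (name == "alexnet_mod") {
    # stages 1-2: conv + relu + batch-norm where the stock net max-pools
    add(op = "conv", p = .param_conv(1L, 16L, 11L), stride = 4L, pad = 5L)
    add(op = "relu")
    add(op = "bn", p = .param_bn(16L))
    add(op = "conv", p = .param_conv(16L, 32L, 5L))
    add(op = "relu")
    add(op = "bn", p = .param_bn(32L))
    add(op = "conv", p = .param_conv(32L, 48L, 3L))
    add(op = "relu")
    add(op = "conv", p = .param_conv(48L, 48L, 3L))
    add(op = "relu")
    add(op = "conv", p = .param_conv(48L, 32L, 3L))
    add(op = "relu")
    add(op = "pool", w = 4L)
    flatL <- .seq_out_len(layers, L) * 32L
    add(op = "flatten")
    add(op = "linear", p = .param_linear(flatL, 128L))
    add(op = "relu")
    add(op = "dropout", rate = 0.5)
    add(op = "linear", p = .param_linear(128L, 64L))
    add(op = "relu")
    add(op = "linear", p = .param_linear(64L, nClasses))
  } else {
    add(op = "conv", p = .param_conv(1L, 16L, 7L), stride = 4L, pad = 3L)
    add(op = "bn", p = .param_bn(16L))
    add(op = "relu")
    add(op = "pool", w = 2L)
    ch <- c(16L, 16L, 32L, 64L, 128L)
    for (stg in 1:4) {
      cin <- ch[stg]; cout <- ch[stg + 1L]
      stride <- if (stg == 1L) 1L else 2L
      b1 <- if (cin == cout && stride == 1L) {
        b <- .plain_resbasic(cout); b$stride <- 1L; b
      } else .plain_resdown(cin, cout, stride)
      add(op = "resblock", p = b1)
      b2 <- .plain_resbasic(cout); b2$stride <- 1L
      add(op = "resblock", p = b2)
    }
    add(op = "gap")
    add(op = "linear", p = .param_linear(128L, nClasses))
  }
  model <- new.env(parent = emptyenv())
  model$type <- name
  model$layers <- layers
  model$cfg <- netConfig(inputLength = L, nClasses = nClasses)
  model$params <- lapply(layers, function(ly) ly$p)
  class(model) <- "libsModel"
  model
}

# residual blocks without SE (identity attention) for the stock ResNet
.plain_resbasic <- function(c) {
  b <- .new_resbasic(c, 1L)
  b$se1 <- .se_identity(c); b$se2 <- .se_identity(c)
  b
}
.plain_resdown <- function(cin, cout, stride) {
  b <- .new_resdown(cin, cout, 1L, stride)
  b$se1 <- .se_identity(cout); b$se2 <- .se_identity(cout)
  b
}

# an SE whose excitation is pinned fully open (weights 2, i.e. scale
# sigmoid(large) ~ 1) would distort; instead use a pass-through marker
.se_identity <- function(c) {
  p <- .new_param(character())
  p$kind <- "se_identity"
  p
}
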