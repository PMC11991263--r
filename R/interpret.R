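#' 1-D Grad-CAM saliency over wavelength
#'
#' Computes class-activation saliency for one spectrum: the gradient of
#' the target class score (pre-softmax logit) with respect to a
#' convolutional feature map is globally averaged per channel to give
#' channel weights; the rectified, weight-summed feature map is linearly
#' interpolated back to the wavelength grid and min-max normalized to
#' \[0, 1\] (normalization is skipped for an identically zero map).
#'
#' @param model a trained multi-scale network from [buildModel()];
#'   the classic sequential CNNs do not expose tap layers and raise an
#'   error.
#' @param spectrum a numeric intensity vector of the model's input
#'   length, or a single-column [SpectralSet-class].
#' @param classIndex 1-based class whose score is explained; default is
#'   the model's predicted class.
#' @param targetLayer `"rsm"` (output of the final residual block, the
#'   default: the deepest convolutional feature map, whose channels are
#'   the most class-selective) or `"multiscale"` (output of the
#'   multi-scale block; shallower, with more generic features).
#' @param stream which input stream's feature map to explain: `"raw"`
#'   (default) or `"diff"` (the backward-difference stream, only when the
#'   model has one).
#' @param wavelengths optional wavelength grid for the result; defaults
#'   to the `SpectralSet`'s grid or the point index.
#' @return a [SaliencyMap-class]
#' @export
gradCam1d <- function(model, spectrum, classIndex = NULL,
                      targetLayer = c("rsm", "multiscale"),
                      stream = c("raw", "diff"), wavelengths = NULL) {
  targetLayer <- match.arg(targetLayer)
  stream <- match.arg(stream)
  stopifnot(inherits(model, "libsModel"))
  if (model$type != "msnet")
    stop(sprintf(
      "gradCam1d: model type '%s' exposes no differentiable target layer",
      model$type), call. = FALSE)
  if (is(spectrum, "SpectralSet")) {
    if (ncol(spectrum) != 1L)
      stop("gradCam1d: supply a single spectrum", call. = FALSE)
    if (is.null(wavelengths)) wavelengths <- wavelengths(spectrum)
    spectrum <- as.vector(intensities(spectrum))
  }
  L <- length(spectrum)
  if (L != model$cfg@inputLength)
    stop("gradCam1d: spectrum length does not match the model input length",
         call. = FALSE)
  if (is.null(wavelengths)) wavelengths <- seq_len(L)
  if (stream == "diff" && !model$cfg@useBackwardDifference)
    stop("gradCam1d: the model has no backward-difference stream",
         call. = FALSE)

  x <- array(spectrum, c(1L, L, 1L))
  fw <- .net_fwd(model, x, training = FALSE, keep = TRUE)
  if (is.null(classIndex))
    classIndex <- which.max(fw$logits[, 1L])
  classIndex <- as.integer(classIndex)
  if (classIndex < 1L || classIndex > nrow(fw$logits))
    stop("gradCam1d: classIndex out of range", call. = FALSE)
  glog <- matrix(0, nrow(fw$logits), 1L)
  glog[classIndex, 1L] <- 1
  params <- .unique_params(model)
  taps <- .net_bwd(model, fw$cache, glog)
  cpp_resblock_clear()
  .zero_grads(params)   # discard the parameter gradients of this probe

  sIdx <- if (stream == "raw") 1L else 2L
  A <- if (targetLayer == "rsm") fw$taps[[sIdx]]$rsm
       else fw$taps[[sIdx]]$multiscale
  gA <- taps[[if (targetLayer == "rsm") sprintf("rsm%d", sIdx)
              else sprintf("ms%d", sIdx)]]
  Am <- matrix(A[, , 1L], dim(A)[1L])
  gAm <- matrix(gA[, , 1L], dim(gA)[1L])
  alpha <- rowMeans(gAm)
  map <- pmax(as.vector(crossprod(Am, alpha)), 0)

  # map coarse positions back to input-grid centers; cubic-spline
  # upsampling recovers sub-cell peak positions that piecewise-linear
  # interpolation would pin to cell centers
  strideTotal <- model$cfg@poolSize *
    if (targetLayer == "rsm") model$cfg@downStride else 1L
  centers <- (seq_along(map) - 0.5) * strideTotal + 0.5
  rel <- if (length(map) >= 4L)
    pmax(stats::spline(centers, map, xout = seq_len(L))$y, 0)
  else approx(centers, map, xout = seq_len(L), rule = 2)$y
  if (max(rel) > 0) rel <- (rel - min(rel)) / (max(rel) - min(rel))
  new("SaliencyMap", wavelengths = as.numeric(wavelengths),
      relevance = rel, classIndex = classIndex,
      targetLayer = paste0(targetLayer, "_", stream))
}

#' @describeIn gradCam1d wavelength grid of a saliency map.
#' @param x a `SaliencyMap`
#' @export
setMethod("wavelengths", "SaliencyMap", function(x) x@wavelengths)

#' @describeIn gradCam1d per-wavelength relevance in \[0, 1\].
#' @export
setMethod("relevance", "SaliencyMap", function(x) x@relevance)

setMethod("show", "SaliencyMap", function(object) {
  pk <- which.max(object@relevance)
  cat(sprintf(
    "SaliencyMap (%s, class %d): %d points, peak relevance at %.2f nm\n",
    object@targetLayer, object@classIndex, length(object@relevance),
    object@wavelengths[pk]))
})

#' Write a saliency map as delimited text
#'
#' @param map a [SaliencyMap-class]
#' @param path output `.csv` path.
#' @return invisibly, `path`.
#' @export
writeSaliency <- function(map, path) {
  stopifnot(is(map, "SaliencyMap"))
  data.table::fwrite(data.table::data.table(
    wavelength_nm = map@wavelengths, relevance = map@relevance), path)
  invisible(path)
}
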