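#' Container for a labeled set of LIBS spectra
#'
#' `SpectralSet` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' a collection of emission spectra acquired on a common wavelength grid.
#' Rows are wavelength points, columns are individual laser shots (spectra).
#' The `"intensity"` assay stores detector counts; `rowData` carries the
#' wavelength grid in nm; `colData` carries per-spectrum metadata: the class
#' (origin) label, the tablet (pressed-pellet replicate) the shot was taken
#' from, an opaque sample id, and the shot index within its tablet.
#'
#' Validity requires a strictly increasing wavelength grid, finite
#' intensities, and one class/tablet label per spectrum.
#'
#' @seealso [SpectralSet()] for construction, [readSpectra()] /
#'   [writeSpectra()] for on-disk round trips, [generateSpectra()] for the
#'   synthetic generator.
#' @export
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
  msg <- character()
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (is.null(wl))
    msg <- c(msg, "rowData must contain a 'wavelength_nm' column")
  else {
    if (anyNA(wl) || any(!is.finite(wl)))
      msg <- c(msg, "wavelengths must be finite")
    if (length(wl) > 1L && any(diff(wl) <= 0))
      msg <- c(msg, "wavelengths must be strictly increasing")
  }
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an 'intensity' assay is required")
  else if (any(!is.finite(SummarizedExperiment::assay(object, "intensity"))))
    msg <- c(msg, "all intensities must be finite")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("class", "tablet", "sample_id", "shot_index"))
    if (!f %in% colnames(cd))
      msg <- c(msg, sprintf("colData must contain '%s'", f))
  if ("class" %in% colnames(cd) && !is.factor(cd$class))
    msg <- c(msg, "'class' must be a factor")
  if (length(msg)) msg else TRUE
})

#' Savitzky-Golay filter object
#'
#' Holds the least-squares smoothing weights of a Savitzky-Golay filter of
#' a given polynomial order and (odd) window length, together with the full
#' window projection matrix used for polynomial-extrapolation edge handling.
#' The `coefficients` slot is the central row of the projection: the
#' convolution weights applied at interior points. These weights sum to 1
#' and are symmetric.
#'
#' @seealso [sgCoefficients()], [sgSmooth()]
#' @export
setClass("SGFilter",
  representation(order = "integer", window = "integer",
                 coefficients = "numeric", projection = "matrix"))

setValidity("SGFilter", function(object) {
  msg <- character()
  if (object@window %% 2L == 0L) msg <- c(msg, "window must be odd")
  if (object@window <= object@order) msg <- c(msg, "window must exceed order")
  if (length(object@coefficients) != object@window)
    msg <- c(msg, "coefficient length must equal window")
  if (abs(sum(object@coefficients) - 1) > 1e-8)
    msg <- c(msg, "coefficients must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic LIBS generator configuration
#'
#' Describes the emission-line inventory, class structure, baseline,
#' noise and replicate design of the synthetic spectrum generator. See
#' [synthConfig()] for field semantics and defaults.
#'
#' @export
setClass("SynthConfig",
  representation(gridStart = "numeric", gridEnd = "numeric",
                 nPoints = "integer", lines = "data.frame",
                 classMultipliers = "matrix", baselineCoeffs = "numeric",
                 noiseSd = "numeric", nClasses = "integer",
                 tabletsPerClass = "integer", shotsPerTablet = "integer",
                 tabletJitterSd = "numeric", classNames = "character",
                 seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (object@gridEnd <= object@gridStart)
    msg <- c(msg, "gridEnd must exceed gridStart")
  need <- c("element", "center_nm", "base_intensity", "width_nm")
  if (!all(need %in% colnames(object@lines)))
    msg <- c(msg, "lines must have columns element, center_nm, base_intensity, width_nm")
  else {
    if (any(object@lines$center_nm < object@gridStart |
            object@lines$center_nm > object@gridEnd))
      msg <- c(msg, "all line centers must lie within the grid range")
    if (any(object@lines$width_nm <= 0))
      msg <- c(msg, "line widths must be positive")
    if (any(object@lines$base_intensity < 0))
      msg <- c(msg, "base intensities must be nonnegative")
  }
  if (!identical(dim(object@classMultipliers),
                 c(object@nClasses, nrow(object@lines))))
    msg <- c(msg, sprintf(
      "classMultipliers must be %d classes x %d lines",
      object@nClasses, nrow(object@lines)))
  if (any(object@classMultipliers < 0))
    msg <- c(msg, "class multipliers must be nonnegative")
  if (length(object@classNames) != object@nClasses)
    msg <- c(msg, "one class name per class required")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Preprocessing configuration
#'
#' Parameters of the spectral preprocessing chain: Savitzky-Golay order and
#' window, baseline-correction method and its controls, the normalization
#' switch, and the stage order. See [preprocessConfig()].
#'
#' @export
setClass("PreprocessConfig",
  representation(sgOrder = "integer", sgWindow = "integer",
                 baselineMethod = "character", baselineDegree = "integer",
                 baselineMaxIter = "integer", baselineTol = "numeric",
                 normalize = "logical", stages = "character"))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@sgWindow %% 2L == 0L) msg <- c(msg, "sgWindow must be odd")
  if (object@sgWindow <= object@sgOrder)
    msg <- c(msg, "sgWindow must exceed sgOrder")
  if (!object@baselineMethod %in%
      c("linear", "polynomial", "iterative_polynomial", "none"))
    msg <- c(msg, "unknown baselineMethod")
  if (object@baselineTol <= 0) msg <- c(msg, "baselineTol must be positive")
  if (!all(object@stages %in% c("normalize", "sg", "baseline")))
    msg <- c(msg, "stages must be drawn from normalize/sg/baseline")
  if (length(msg)) msg else TRUE
})

#' Network architecture configuration
#'
#' Hyperparameters of the dual-stream multi-scale residual channel-attention
#' network. See [netConfig()] for semantics and defaults; the `useBackwardDifference`
#' and `useMultiscale` switches realize the ablation arms.
#'
#' @export
setClass("NetConfig",
  representation(inputLength = "integer", kernelSizes = "integer",
                 branchChannels = "integer", seReduction = "integer",
                 diffStep = "integer", dropoutRate = "numeric",
                 mlpHidden = "integer", shareStreamWeights = "logical",
                 useBackwardDifference = "logical", useMultiscale = "logical",
                 nClasses = "integer", poolSize = "integer",
                 downChannels = "integer", downStride = "integer",
                 headPool = "character"))

setValidity("NetConfig", function(object) {
  msg <- character()
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (any(object@kernelSizes %% 2L == 0L))
    msg <- c(msg, "kernel sizes must be odd")
  if (object@diffStep < 1L) msg <- c(msg, "diffStep must be a positive integer")
  if (object@seReduction < 1L) msg <- c(msg, "seReduction must be >= 1")
  merged <- length(object@kernelSizes) * object@branchChannels
  if (merged %% object@seReduction != 0L ||
      object@downChannels %% object@seReduction != 0L)
    msg <- c(msg, "channel counts must be divisible by seReduction")
  if (!object@headPool %in% c("pnorm", "max", "avg"))
    msg <- c(msg, "headPool must be 'pnorm', 'max' or 'avg'")
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' Optimization and data-split settings for network training: SGD learning
#' rate and momentum, epoch and batch counts, the train/validation/test
#' split ratios, the RNG seed, and whether splitting is tablet-aware.
#' See [trainConfig()].
#'
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", epochs = "integer",
                 batchSize = "integer", momentum = "numeric",
                 splitRatios = "numeric", seed = "integer",
                 groupAwareSplit = "logical"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (abs(sum(object@splitRatios) - 1) > 1e-8)
    msg <- c(msg, "splitRatios must sum to 1")
  if (!length(object@splitRatios) %in% 2:3)
    msg <- c(msg, "splitRatios must have 2 or 3 entries")
  if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Classifier evaluation result
#'
#' Confusion counts (rows = true class, columns = predicted class),
#' overall accuracy as a fraction, and optional per-epoch train/validation
#' accuracy traces. For the two-class case the first class name is the
#' "positive" class, so TP sits at `counts[1, 1]` and TN at `counts[2, 2]`.
#'
#' @export
setClass("ClassifierEval",
  representation(counts = "matrix", accuracy = "numeric",
                 traces = "data.frame"))

setValidity("ClassifierEval", function(object) {
  msg <- character()
  if (nrow(object@counts) != ncol(object@counts))
    msg <- c(msg, "counts must be square")
  if (length(object@accuracy) != 1L ||
      object@accuracy < 0 || object@accuracy > 1)
    msg <- c(msg, "accuracy must be a fraction in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-wavelength saliency map
#'
#' Output of 1-D Grad-CAM: a relevance value per wavelength, min-max
#' normalized to \[0, 1\] unless the raw map is identically zero.
#'
#' @seealso [gradCam1d()]
#' @export
setClass("SaliencyMap",
  representation(wavelengths = "numeric", relevance = "numeric",
                 classIndex = "integer", targetLayer = "character"))

setValidity("SaliencyMap", function(object) {
  msg <- character()
  if (length(object@wavelengths) != length(object@relevance))
    msg <- c(msg, "wavelengths and relevance must have equal length")
  if (any(object@relevance < -1e-12))
    msg <- c(msg, "relevance must be nonnegative")
  if (max(object@relevance) > 1 + 1e-12)
    msg <- c(msg, "relevance must not exceed 1")
  if (length(msg)) msg else TRUE
})
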