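#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("spectrumClasses", function(x) standardGeneric("spectrumClasses"))

#' @export
setGeneric("tabletIds", function(x) standardGeneric("tabletIds"))

#' @export
setGeneric("shotIndices", function(x) standardGeneric("shotIndices"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @export
setGeneric("accuracyTraces", function(x) standardGeneric("accuracyTraces"))

#' @export
setGeneric("relevance", function(x) standardGeneric("relevance"))
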