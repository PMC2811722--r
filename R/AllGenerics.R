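#' @rdname VocStudy-class
#' @param x,object a \linkS4class{VocStudy} or \linkS4class{SubtractedMatrix}
#' @export
setGeneric("peakIds", function(x) standardGeneric("peakIds"))

#' @rdname VocStudy-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname VocStudy-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname VocStudy-class
#' @export
setGeneric("plantedDifferential",
           function(x) standardGeneric("plantedDifferential"))

#' @rdname VocStudy-class
#' @export
setGeneric("plantedInteraction",
           function(x) standardGeneric("plantedInteraction"))

#' @rdname SubtractedMatrix-class
#' @export
setGeneric("subtractedValues", function(x) standardGeneric("subtractedValues"))

#' @rdname SubtractedMatrix-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname SubtractedMatrix-class
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname SubtractedMatrix-class
#' @export
setGeneric("sampleModels", function(x) standardGeneric("sampleModels"))

#' Remove the shared collection-period ("term") effect by per-animal
#' subtraction
#'
#' @param early,late processed peak tables (samples x peaks) for the early and
#'   terminal collection stages, or a \linkS4class{VocStudy} (with `late`
#'   missing) from which both stage tables of one tumor model are taken.
#' @param ... passed to methods.
#' @return a \linkS4class{SubtractedMatrix} of per-animal late-minus-early
#'   values.
#' @export
setGeneric("subtractTermEffect",
           function(early, late, ...) standardGeneric("subtractTermEffect"))
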