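#' @include AllGenerics.R
NULL

#' VocStudy: a four-group, two-timepoint volatile-compound study
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' GC/MS peak-height study: the `"intensity"` assay stores linear-scale peak
#' heights (peaks in rows, one column per sample-by-timepoint measurement)
#' and `colData` carries `sample_id`, `model` (tumor model), `condition`
#' (`tumor`/`placebo`) and `timepoint` (`early`/`late`). Synthetic studies
#' additionally carry the generating design, effect specification, seed and
#' ground-truth peak sets in `metadata()`.
#'
#' The design is required to be balanced: every (model, condition) group has
#' the same number of animals, each measured at both timepoints, and all
#' groups share one peak-identifier list (the assay rownames).
#'
#' @seealso [simulateStudy()], [subtractTermEffect()], [readPeakTable()]
#' @aliases peakIds intensities sampleInfo plantedDifferential
#'   plantedInteraction
#' @export
setClass("VocStudy", contains = "SummarizedExperiment")

setValidity("VocStudy", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "model", "condition", "timepoint")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("missing colData column(s): %s",
                   paste(miss, collapse = ", ")))
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  if (!all(cd$condition %in% c("tumor", "placebo")))
    return("condition must be 'tumor' or 'placebo'")
  if (!all(cd$timepoint %in% c("early", "late")))
    return("timepoint must be 'early' or 'late'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("peak identifiers (rownames) must be present and unique")
  cnt <- table(cd$model, cd$condition, cd$timepoint)
  if (length(unique(as.vector(cnt))) != 1L)
    return("unbalanced design: all (model, condition, timepoint) cells must have the same number of samples")
  key <- paste(cd$sample_id, cd$timepoint)
  if (anyDuplicated(key))
    return("duplicate (sample_id, timepoint) measurements")
  truth <- S4Vectors::metadata(object)$truth
  if (!is.null(truth)) {
    bad <- setdiff(unlist(truth), rownames(object))
    if (length(bad))
      return(sprintf("ground-truth peaks not in peak list: %s",
                     paste(bad, collapse = ", ")))
  }
  TRUE
})

#' @rdname VocStudy-class
#' @export
setMethod("peakIds", "VocStudy", function(x) rownames(x))

#' @rdname VocStudy-class
#' @export
setMethod("intensities", "VocStudy",
          function(x) SummarizedExperiment::assay(x, "intensity"))

#' @rdname VocStudy-class
#' @export
setMethod("sampleInfo", "VocStudy", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname VocStudy-class
#' @export
setMethod("plantedDifferential", "VocStudy", function(x)
  S4Vectors::metadata(x)$truth$differential)

#' @rdname VocStudy-class
#' @export
setMethod("plantedInteraction", "VocStudy", function(x)
  S4Vectors::metadata(x)$truth$interaction)

setMethod("show", "VocStudy", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("VocStudy:", nrow(object), "peaks,",
      length(unique(cd$sample_id)), "animals,",
      length(unique(cd$model)), "tumor model(s), 2 timepoints\n")
  md <- S4Vectors::metadata(object)
  if (!is.null(md$truth))
    cat("  planted: ", length(md$truth$differential), " differential, ",
        length(md$truth$interaction), " interaction peak(s); seed ",
        md$seed, "\n", sep = "")
  callNextMethod()
})

#' SubtractedMatrix: per-animal term-effect-subtracted peak values
#'
#' Holds the per-animal, per-peak subtracted statistic R = late - early
#' (samples in rows, peaks in columns), the tumor-model and condition label
#' of every animal, whether peak columns have been z-scored, and a
#' provenance note naming the stage tables it came from.
#'
#' @slot values numeric matrix, samples x peaks.
#' @slot condition factor (`tumor`/`placebo`) per sample; may be empty when
#'   the matrix was built from bare stage tables.
#' @slot model factor (tumor model) per sample; may be empty.
#' @slot normalized logical; `TRUE` after [normalizeSubtracted()].
#' @slot provenance character note on the input tables.
#' @seealso [subtractTermEffect()], [normalizeSubtracted()], [screenPeaks()]
#' @aliases subtractedValues isNormalized sampleConditions sampleModels
#' @export
setClass("SubtractedMatrix",
         representation(values = "matrix", condition = "factor",
                        model = "factor", normalized = "logical",
                        provenance = "character"),
         prototype(normalized = FALSE, provenance = NA_character_))

setValidity("SubtractedMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("peak identifiers (colnames) must be present and unique")
  n <- nrow(v)
  for (s in c("condition", "model")) {
    len <- length(slot(object, s))
    if (!len %in% c(0L, n))
      return(sprintf("%s labels must be empty or one per sample", s))
  }
  if (length(object@normalized) != 1L) return("normalized must be a flag")
  TRUE
})

#' @rdname SubtractedMatrix-class
#' @export
setMethod("subtractedValues", "SubtractedMatrix", function(x) x@values)

#' @rdname SubtractedMatrix-class
#' @export
setMethod("isNormalized", "SubtractedMatrix", function(x) x@normalized)

#' @rdname SubtractedMatrix-class
#' @export
setMethod("sampleConditions", "SubtractedMatrix", function(x) x@condition)

#' @rdname SubtractedMatrix-class
#' @export
setMethod("sampleModels", "SubtractedMatrix", function(x) x@model)

#' @rdname SubtractedMatrix-class
#' @export
setMethod("peakIds", "SubtractedMatrix", function(x) colnames(x@values))

setMethod("show", "SubtractedMatrix", function(object) {
  cat("SubtractedMatrix: ", nrow(object@values), " samples x ",
      ncol(object@values), " peaks (",
      if (object@normalized) "normalized" else "unnormalized", ")\n",
      sep = "")
  if (length(object@condition))
    cat("  conditions:",
        paste(names(table(object@condition)), table(object@condition),
              sep = "=", collapse = ", "), "\n")
  if (!is.na(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' PcaModel: a fitted principal-component projection
#'
#' Centering vector, orthonormal loadings (sign convention: the
#' largest-magnitude entry of each loading is positive) and per-component
#' explained-variance fractions from the covariance eigendecomposition.
#'
#' @slot center per-feature training means.
#' @slot rotation features x components loading matrix.
#' @slot sdev per-component score standard deviations.
#' @slot varExplained fractions of total variance, non-increasing.
#' @seealso [pcaFit()], [pcaProject()]
#' @export
setClass("PcaModel",
         representation(center = "numeric", rotation = "matrix",
                        sdev = "numeric", varExplained = "numeric"))

setValidity("PcaModel", function(object) {
  if (length(object@center) != nrow(object@rotation))
    return("center length must match rotation rows")
  k <- ncol(object@rotation)
  if (length(object@sdev) != k || length(object@varExplained) != k)
    return("sdev/varExplained length must match number of components")
  if (is.unsorted(rev(object@varExplained), strictly = FALSE))
    return("explained-variance fractions must be non-increasing")
  if (sum(object@varExplained) > 1 + 1e-8)
    return("explained-variance fractions must sum to at most 1")
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(k))) > 1e-6) return("loadings must be orthonormal")
  TRUE
})

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel:", nrow(object@rotation), "features,",
      ncol(object@rotation), "components\n  varExplained:",
      paste(sprintf("%.3f", object@varExplained), collapse = " "), "\n")
})

#' RbfSvm: a fitted soft-margin Gaussian-kernel support vector machine
#'
#' The decision function is
#' \deqn{f(x) = \sum_s \alpha_s y_s \exp(-\sigma \|x_s - x\|^2) + b,}
#' with dual coefficients \eqn{0 \le \alpha_s \le C} obtained by sequential
#' minimal optimization of the C-SVM dual; samples are classified by
#' \eqn{\mathrm{sign}(f)}. Only support vectors (\eqn{\alpha_s > 0}) are
#' stored. `sigma` multiplies the squared Euclidean distance (the `rbfdot`
#' convention of the kernlab library).
#'
#' @slot sigma,cost kernel width parameter and soft-margin penalty.
#' @slot svX support-vector coordinates (rows).
#' @slot svY support-vector labels in \{-1, +1\}.
#' @slot svAlpha dual coefficients of the support vectors, in (0, C].
#' @slot b bias term.
#' @slot objective value of the dual objective at the solution.
#' @slot gap final KKT violation (duality-gap surrogate) of the solver.
#' @slot tol requested solver tolerance.
#' @slot iterations SMO iterations used.
#' @slot nTrain training-set size.
#' @slot positiveLabel original label coded as +1.
#' @seealso [svmTrain()], [svmPredict()]
#' @export
setClass("RbfSvm",
         representation(sigma = "numeric", cost = "numeric", svX = "matrix",
                        svY = "numeric", svAlpha = "numeric", b = "numeric",
                        objective = "numeric", gap = "numeric",
                        tol = "numeric", iterations = "integer",
                        nTrain = "integer", positiveLabel = "character"))

setValidity("RbfSvm", function(object) {
  ns <- nrow(object@svX)
  if (length(object@svY) != ns || length(object@svAlpha) != ns)
    return("support-vector slots have inconsistent lengths")
  if (!all(object@svY %in% c(-1, 1))) return("svY must be -1/+1")
  if (any(object@svAlpha < -1e-8 | object@svAlpha > object@cost + 1e-8))
    return("dual coefficients must lie in [0, C]")
  if (object@sigma <= 0 || object@cost <= 0) return("sigma and C must be > 0")
  TRUE
})

setMethod("show", "RbfSvm", function(object) {
  cat(sprintf(
    "RbfSvm: sigma=%g C=%g | %d support vectors of %d samples | b=%.4g\n",
    object@sigma, object@cost, nrow(object@svX), object@nTrain, object@b))
  cat(sprintf("  dual objective %.6g (KKT gap %.2g, %d iterations)\n",
              object@objective, object@gap, object@iterations))
})
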