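# Term-effect subtraction, per-peak normalization, univariate screening.

stageMax <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, as.matrix)
    return(Reduce(pmax, x))  # per-sample maximum across collections
  }
  as.matrix(x)
}

#' @describeIn subtractTermEffect subtract two stage tables (samples x peaks)
#'   with identical sample and peak identifiers. Each argument may also be a
#'   list of matrices from repeated collections within a stage, in which case
#'   each cell is the per-sample maximum across collections before
#'   subtraction.
#' @param condition,model optional per-sample labels attached to the result.
#' @export
setMethod("subtractTermEffect", signature("ANY", "ANY"),
          function(early, late, condition = factor(), model = factor(), ...) {
  e <- stageMax(early)
  l <- stageMax(late)
  if (!identical(dim(e), dim(l)))
    vpDataError("stage tables differ in shape: early %dx%d vs late %dx%d",
                nrow(e), ncol(e), nrow(l), ncol(l))
  mism <- function(what, a, b) {
    bad <- union(setdiff(a, b), setdiff(b, a))
    if (length(bad))
      vpDataError("%s identifiers differ between stages: %s", what,
                  paste(bad, collapse = ", "))
    if (!identical(a, b))
      vpDataError("%s identifiers are ordered differently between stages", what)
  }
  mism("sample", rownames(e), rownames(l))
  mism("peak", colnames(e), colnames(l))
  methods::new("SubtractedMatrix", values = l - e,
               condition = as.factor(condition), model = as.factor(model),
               normalized = FALSE, provenance = "late - early stage tables")
})

#' @describeIn subtractTermEffect build the analysis set of one tumor model
#'   from a study: intensities are log-transformed ([logTransform()]) and
#'   per-sample intensity-corrected ([normalizeIntensity()]), then the early
#'   table is subtracted from the late table animal by animal.
#' @param tumorModel which tumor model to extract when `early` is a
#'   \linkS4class{VocStudy}; default the study's first model.
#' @param offset log-transform offset.
#' @param correctIntensity row-center each sample before subtraction.
#' @export
setMethod("subtractTermEffect", signature("VocStudy", "missing"),
          function(early, late, tumorModel = NULL, offset = 1,
                   correctIntensity = TRUE, ...) {
  study <- early
  cd <- sampleInfo(study)
  if (is.null(tumorModel)) tumorModel <- sort(unique(cd$model))[1L]
  if (!tumorModel %in% cd$model)
    vpDataError("tumor model '%s' not present in study", tumorModel)
  sel <- cd$model == tumorModel
  x <- t(intensities(study)[, sel, drop = FALSE])  # samples x peaks
  x <- logTransform(x, offset)
  if (correctIntensity) x <- normalizeIntensity(x)
  cd <- cd[sel, ]
  ord <- order(cd$sample_id)
  pick <- function(tp) {
    idx <- ord[cd$timepoint[ord] == tp]
    m <- x[idx, , drop = FALSE]
    rownames(m) <- cd$sample_id[idx]
    m
  }
  e <- pick("early")
  l <- pick("late")
  out <- subtractTermEffect(e, l)
  out@condition <- factor(cd$condition[ord][cd$timepoint[ord] == "early"])
  out@model <- factor(rep(tumorModel, nrow(e)))
  out@provenance <- sprintf("model %s: late - early (offset %g, %s)",
                            tumorModel, offset,
                            if (correctIntensity) "intensity-corrected"
                            else "raw log")
  methods::validObject(out)
  out
})

#' Z-score the subtracted values peak by peak
#'
#' Each peak column is centered and scaled to unit variance across all pooled
#' samples of the analysis set (population standard deviation, so the column
#' `(1, 2, 3)` becomes `(-1.2247, 0, 1.2247)`). Zero-variance columns are set
#' to all zeros with a warning. Idempotent.
#'
#' @param R a \linkS4class{SubtractedMatrix} or bare samples x peaks matrix.
#' @return the same type, flagged as normalized.
#' @export
normalizeSubtracted <- function(R) {
  isObj <- is(R, "SubtractedMatrix")
  v <- if (isObj) R@values else as.matrix(R)
  ctr <- colMeans(v)
  v <- sweep(v, 2L, ctr, "-")
  s <- sqrt(colMeans(v^2))
  flat <- s == 0 | !is.finite(s)
  if (any(flat)) {
    warning(sprintf("zero-variance peak column(s) set to 0: %s",
                    paste(colnames(v)[flat], collapse = ", ")),
            call. = FALSE)
    s[flat] <- 1
  }
  v <- sweep(v, 2L, s, "/")
  v[, flat] <- 0
  if (!isObj) return(v)
  R@values <- v
  R@normalized <- TRUE
  R
}

#' Univariate screening of peaks between tumor and placebo
#'
#' Tests every peak of a (normalized) subtracted matrix between the two
#' classes of one tumor model with a two-sided two-sample test; the default is
#' Welch's t, robust to unequal variances. No multiple-testing correction is
#' applied: following the study design this mirrors, peaks are screened at a
#' stringent raw threshold (default `alpha = 1e-4`).
#'
#' @param R \linkS4class{SubtractedMatrix} (its condition labels are used) or
#'   a samples x peaks matrix.
#' @param labels two-class labels per sample; required for bare matrices.
#' @param alpha selection threshold on the raw p-value.
#' @param method `"welch"` (default), `"pooled"` t, or `"wilcoxon"`.
#' @return data.frame sorted by p ascending with columns `peak`, `meanTumor`,
#'   `meanPlacebo` (class means, named after the actual labels when they are
#'   not tumor/placebo), `statistic`, `p`, `selected`.
#' @examples
#' study <- simulateStudy(studyDesign(nPerGroup = 10, nPeaks = 8, seed = 3))
#' R <- normalizeSubtracted(subtractTermEffect(study, tumorModel = "A"))
#' head(screenPeaks(R, alpha = 1e-2))
#' @export
screenPeaks <- function(R, labels = NULL, alpha = 1e-4,
                        method = c("welch", "pooled", "wilcoxon")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) vpConfigError("alpha must be in (0, 1)")
  v <- if (is(R, "SubtractedMatrix")) R@values else as.matrix(R)
  if (is.null(labels)) {
    if (!is(R, "SubtractedMatrix") || !length(R@condition))
      vpDataError("labels are required when R carries no condition labels")
    labels <- R@condition
  }
  pm <- labelsToPM(labels)
  if (min(table(pm)) < 2L)
    vpDataError("each class needs at least 2 samples for screening")
  pos <- pm > 0
  res <- t(vapply(seq_len(ncol(v)), function(j) {
    a <- v[pos, j]
    b <- v[!pos, j]
    switch(method,
           welch = {
             tt <- t.test(a, b, var.equal = FALSE)
             c(tt$statistic, tt$p.value)
           },
           pooled = {
             tt <- t.test(a, b, var.equal = TRUE)
             c(tt$statistic, tt$p.value)
           },
           wilcoxon = {
             wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
             c(wt$statistic, wt$p.value)
           })
  }, numeric(2)))
  posName <- attr(pm, "positive")
  out <- data.frame(peak = colnames(v),
                    meanTumor = colMeans(v[pos, , drop = FALSE]),
                    meanPlacebo = colMeans(v[!pos, , drop = FALSE]),
                    statistic = res[, 1L], p = res[, 2L],
                    row.names = NULL)
  if (!identical(posName, "tumor") && !identical(posName, "+1"))
    names(out)[2:3] <- paste0("mean", c(posName, "Other"))
  out$selected <- out$p < alpha
  out[order(out$p, out$peak), , drop = FALSE]
}

#' Selected peak identifiers from a screening report
#'
#' @param report data.frame from [screenPeaks()].
#' @return character vector of selected peaks, sorted by p ascending.
#' @export
selectedPeaks <- function(report) report$peak[report$selected]
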