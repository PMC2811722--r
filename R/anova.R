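# Balanced two-way ANOVA with interaction, per peak. Only the balanced 2x2
# layout of the study design (condition x tumor model, equal cell counts) is
# supported; the decomposition is the exact closed form from cell means.

#' Balanced 2x2 two-way ANOVA with interaction, per peak
#'
#' Decomposes each peak's normalized subtracted values into condition
#' (tumor/placebo), tumor-model, and interaction sums of squares from the
#' cell means of the balanced 2x2 layout:
#' \deqn{SS_A = 2n\sum_i(\bar y_{i..}-\bar y)^2,\quad
#'       SS_{AB} = n\sum_{ij}(\bar y_{ij.}-\bar y_{i..}-\bar y_{.j.}+\bar y)^2,}
#' with `F = MS_effect / MS_error` on (1, N-4) degrees of freedom. A
#' significant interaction flags the peak as responding differently to tumor
#' development in the two models (tumor-type specificity).
#'
#' @param values numeric vector (one peak) or samples x peaks matrix, e.g.
#'   pooled normalized subtracted values of both models; a
#'   \linkS4class{SubtractedMatrix} may be given, in which case its labels
#'   are used.
#' @param condition,model two-level factors per sample; required unless
#'   `values` carries them. All four cells must be non-empty and equally
#'   sized (the design of the emulated study); unbalanced layouts are
#'   rejected.
#' @param loose,strict interaction p-value thresholds used for the
#'   `sigLoose`/`sigStrict` flags (defaults 0.05 and 0.002).
#' @return data.frame, one row per peak: sums of squares (`ssCondition`,
#'   `ssModel`, `ssInteraction`, `ssError`), their df, F and p for each
#'   effect, and interaction flags at the two thresholds.
#' @examples
#' study <- simulateStudy(studyDesign(nPerGroup = 10, nPeaks = 6, seed = 2))
#' R <- pooledSubtracted(study)
#' head(twoWayAnova(R))
#' @export
twoWayAnova <- function(values, condition = NULL, model = NULL,
                        loose = 0.05, strict = 0.002) {
  if (is(values, "SubtractedMatrix")) {
    if (is.null(condition)) condition <- values@condition
    if (is.null(model)) model <- values@model
    values <- values@values
  }
  v <- as.matrix(values)
  if (is.null(colnames(v))) colnames(v) <- sprintf("P%02d", seq_len(ncol(v)))
  condition <- droplevels(as.factor(condition))
  model <- droplevels(as.factor(model))
  n <- nrow(v)
  if (length(condition) != n || length(model) != n)
    vpDataError("condition and model labels must match the number of samples")
  if (nlevels(condition) != 2L || nlevels(model) != 2L)
    vpDataError("need exactly two conditions and two tumor models")
  cellCount <- table(condition, model)
  if (length(unique(as.vector(cellCount))) != 1L || any(cellCount == 0))
    vpDataError("unbalanced 2x2 layout (cell counts %s); only the balanced design is supported",
                paste(as.vector(cellCount), collapse = "/"))
  nc <- as.vector(cellCount)[1L]
  dfErr <- n - 4L
  if (dfErr < 1L) vpDataError("need more than one observation per cell")

  iA <- as.integer(condition)          # 1/2
  iB <- as.integer(model)
  cellOf <- (iA - 1L) * 2L + iB        # 1..4 cell index

  res <- t(vapply(seq_len(ncol(v)), function(j) {
    y <- v[, j]
    cm <- vapply(1:4, function(c) mean(y[cellOf == c]), numeric(1))
    cmM <- matrix(cm, 2, 2, byrow = TRUE)  # rows condition, cols model
    gm <- mean(cm)                         # balanced: grand mean of cells
    am <- rowMeans(cmM)
    bm <- colMeans(cmM)
    ssA <- 2 * nc * sum((am - gm)^2)
    ssB <- 2 * nc * sum((bm - gm)^2)
    inter <- sweep(sweep(cmM, 1L, am, "-"), 2L, bm, "-") + gm
    ssAB <- nc * sum(inter^2)
    ssE <- sum((y - cm[cellOf])^2)
    msE <- ssE / dfErr
    Fs <- c(ssA, ssB, ssAB) / msE
    c(ssA, ssB, ssAB, ssE, Fs, pf(Fs, 1, dfErr, lower.tail = FALSE))
  }, numeric(10)))

  out <- data.frame(
    peak = colnames(v),
    ssCondition = res[, 1L], ssModel = res[, 2L], ssInteraction = res[, 3L],
    ssError = res[, 4L], dfEffect = 1L, dfError = dfErr,
    fCondition = res[, 5L], fModel = res[, 6L], fInteraction = res[, 7L],
    pCondition = res[, 8L], pModel = res[, 9L], pInteraction = res[, 10L],
    row.names = NULL)
  out$sigLoose <- out$pInteraction < loose
  out$sigStrict <- out$pInteraction < strict
  out
}

#' Screen peaks for tumor-model-specific (interaction) effects
#'
#' Splits a per-peak ANOVA table into the peaks whose interaction passes a
#' loose threshold and the subset passing a strict threshold, each sorted by
#' interaction p ascending. The strict list controls for false positives when
#' many peaks are tested at the loose level.
#'
#' @param results data.frame from [twoWayAnova()].
#' @param loose,strict interaction p-value thresholds.
#' @return list with character vectors `loose` and `strict`
#'   (`strict` is always a subset of `loose`).
#' @export
interactionScreen <- function(results, loose = 0.05, strict = 0.002) {
  if (strict > loose)
    vpConfigError("strict threshold must not exceed the loose threshold")
  ord <- results[order(results$pInteraction, results$peak), ]
  list(loose = ord$peak[ord$pInteraction < loose],
       strict = ord$peak[ord$pInteraction < strict])
}

#' Pooled subtracted matrix across both tumor models
#'
#' Convenience for the interaction analysis: subtracts the term effect within
#' each model of a study, stacks the animals, and z-scores peaks over the
#' pooled set.
#'
#' @param study a \linkS4class{VocStudy} with two tumor models.
#' @param ... passed to the study method of [subtractTermEffect()].
#' @return a normalized \linkS4class{SubtractedMatrix} with condition and
#'   model labels for all animals.
#' @export
pooledSubtracted <- function(study, ...) {
  mods <- sort(unique(sampleInfo(study)$model))
  parts <- lapply(mods, function(m)
    subtractTermEffect(study, tumorModel = m, ...))
  vals <- do.call(rbind, lapply(parts, function(p) p@values))
  out <- methods::new(
    "SubtractedMatrix", values = vals,
    condition = factor(unlist(lapply(parts, function(p)
      as.character(p@condition)))),
    model = factor(unlist(lapply(parts, function(p)
      as.character(p@model)))),
    normalized = FALSE,
    provenance = sprintf("pooled models %s", paste(mods, collapse = "+")))
  normalizeSubtracted(out)
}
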