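#' Describe the layout of a synthetic volatile-compound study
#'
#' Captures the emulated design: two tumor models, tumor and placebo
#' conditions, a fixed number of animals per group sampled at an early and a
#' terminal collection period, and a shared peak list.
#'
#' @param models character identifiers of the tumor models (default two,
#'   `"A"` and `"B"`).
#' @param nPerGroup animals per (model, condition) group; each is measured at
#'   both timepoints. Must be at least 2.
#' @param nPeaks number of quantified peaks shared by every group.
#' @param seed integer seed used by [simulateStudy()] unless overridden.
#' @return an object of class `StudyDesign`.
#' @examples
#' studyDesign(nPerGroup = 25, nPeaks = 47)
#' @export
studyDesign <- function(models = c("A", "B"), nPerGroup = 25, nPeaks = 47,
                        seed = 1L) {
  models <- as.character(models)
  if (!length(models) || anyDuplicated(models))
    vpConfigError("models must be a non-empty set of unique identifiers")
  if (nPerGroup < 2) vpConfigError("nPerGroup must be >= 2, got %s", nPerGroup)
  if (nPeaks < 1) vpConfigError("nPeaks must be >= 1, got %s", nPeaks)
  structure(list(models = models, conditions = c("tumor", "placebo"),
                 nPerGroup = as.integer(nPerGroup),
                 nPeaks = as.integer(nPeaks), seed = as.integer(seed)),
            class = "StudyDesign")
}

#' @export
print.StudyDesign <- function(x, ...) {
  cat(sprintf(
    "StudyDesign: %d model(s) x {tumor, placebo} x %d animals, %d peaks, 2 timepoints (seed %d)\n",
    length(x$models), x$nPerGroup, x$nPeaks, x$seed))
  invisible(x)
}

#' Per-peak effect specification for the study generator
#'
#' All effects act on the natural-log intensity scale. For peak p the
#' log-intensity of a sample in group (model m, condition c) at timepoint t is
#' \deqn{\mu_p + \tau_p [t=late] + (\delta_p + \gamma_{p,m}) [t=late, c=tumor]
#'   + \varepsilon, \quad \varepsilon \sim N(0, \sigma_p^2),}
#' so \eqn{\tau_p} is the collection-period ("term") effect shared by tumor
#' and placebo groups, \eqn{\delta_p} the shared tumor effect (negative values
#' encode the predominant tumor-associated down-regulation), and
#' \eqn{\gamma_{p,m}} a model-specific (interaction) tumor effect constrained
#' to sum to zero across models, mirroring the sum-to-zero ANOVA
#' parameterization.
#'
#' Defaults emulate the study design this package targets: 47 peaks, 11
#' differential peaks at \eqn{|\delta_p| = 3\sigma_p} (9 down-regulated, 2
#' up-regulated) and 4 interaction peaks with \eqn{|\gamma_{p,m}| = 1.1};
#' baseline and term-effect patterns are smooth deterministic curves so equal
#' designs always mean equal effect specifications.
#'
#' @param nPeaks number of peaks.
#' @param models tumor-model identifiers (columns of the interaction matrix).
#' @param mu per-peak baseline log intensity.
#' @param tau per-peak term effect applied to every group at the late
#'   timepoint.
#' @param sigma per-peak log-scale noise standard deviation, recycled to
#'   `nPeaks`; must be positive.
#' @param differentialPeaks indices of peaks carrying the shared tumor effect.
#' @param delta either a full length-`nPeaks` vector of shared tumor effects,
#'   or the magnitudes to plant on `differentialPeaks` (sign pattern: all but
#'   the last `nUp` down-regulated).
#' @param nUp of the planted differential peaks, how many are up-regulated.
#' @param interactionPeaks indices of peaks carrying a model-specific effect.
#' @param gamma either a full `nPeaks` x `length(models)` matrix with zero row
#'   sums, or a single magnitude planted with alternating sign across the
#'   interaction peaks (and opposite sign across models).
#' @return an object of class `EffectSpec`.
#' @examples
#' spec <- effectSpec()
#' spec$delta[spec$differentialPeaks]
#' @export
effectSpec <- function(nPeaks = 47, models = c("A", "B"),
                       mu = 5 + 1.2 * sin(seq_len(nPeaks)),
                       tau = 0.6 * cos(0.7 * seq_len(nPeaks)),
                       sigma = 0.5, differentialPeaks = NULL,
                       delta = NULL, nUp = 2,
                       interactionPeaks = intersect(c(1, 7, 29, 33),
                                                    seq_len(nPeaks)),
                       gamma = 1.1) {
  nPeaks <- as.integer(nPeaks)
  models <- as.character(models)
  sigma <- rep_len(as.numeric(sigma), nPeaks)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    vpConfigError("noise sd sigma must be positive and finite")
  if (is.null(differentialPeaks)) {
    idx <- if (nPeaks >= 2) seq(2L, nPeaks, by = 4L) else integer(0)
    differentialPeaks <- idx[seq_len(min(11L, length(idx)))]
  }
  if (length(mu) != nPeaks || length(tau) != nPeaks)
    vpConfigError("mu and tau must have length nPeaks = %d", nPeaks)
  differentialPeaks <- as.integer(differentialPeaks)
  interactionPeaks <- as.integer(interactionPeaks)
  if (length(differentialPeaks) &&
      (min(differentialPeaks) < 1 || max(differentialPeaks) > nPeaks))
    vpConfigError("differentialPeaks out of range")
  if (length(interactionPeaks) &&
      (min(interactionPeaks) < 1 || max(interactionPeaks) > nPeaks))
    vpConfigError("interactionPeaks out of range")

  if (is.null(delta)) {
    delta <- numeric(nPeaks)
    k <- length(differentialPeaks)
    if (k) {
      sgn <- rep(-1, k)
      if (nUp > 0) sgn[seq.int(k - min(nUp, k) + 1L, k)] <- 1
      delta[differentialPeaks] <- sgn * 3 * sigma[differentialPeaks]
    }
  } else if (length(delta) != nPeaks) {
    d <- numeric(nPeaks)
    d[differentialPeaks] <- rep_len(delta, length(differentialPeaks))
    delta <- d
  }

  if (is.matrix(gamma)) {
    if (nrow(gamma) != nPeaks || ncol(gamma) != length(models))
      vpConfigError("gamma matrix must be nPeaks x length(models)")
    if (max(abs(rowSums(gamma))) > 1e-8)
      vpConfigError("gamma rows must sum to zero across models")
  } else {
    g <- matrix(0, nPeaks, length(models))
    if (length(interactionPeaks) && length(models) == 2L) {
      sgn <- rep_len(c(1, -1), length(interactionPeaks))
      g[interactionPeaks, 1L] <- sgn * as.numeric(gamma)
      g[interactionPeaks, 2L] <- -sgn * as.numeric(gamma)
    } else if (length(interactionPeaks)) {
      vpConfigError("scalar gamma requires exactly two models; supply a sum-to-zero matrix otherwise")
    }
    gamma <- g
  }
  colnames(gamma) <- models

  structure(list(nPeaks = nPeaks, models = models, mu = as.numeric(mu),
                 tau = as.numeric(tau), sigma = sigma,
                 delta = as.numeric(delta), gamma = gamma,
                 differentialPeaks = sort(differentialPeaks),
                 interactionPeaks = sort(interactionPeaks)),
            class = "EffectSpec")
}

#' @export
print.EffectSpec <- function(x, ...) {
  cat(sprintf(
    "EffectSpec: %d peaks | %d differential (delta %s) | %d interaction (|gamma| %s) | sigma %s\n",
    x$nPeaks, length(x$differentialPeaks),
    paste(format(unique(round(x$delta[x$differentialPeaks], 3))),
          collapse = "/"),
    length(x$interactionPeaks),
    format(max(abs(x$gamma))), format(unique(round(x$sigma, 3)))))
  invisible(x)
}

#' Simulate a seeded synthetic peak-height study
#'
#' Draws every (animal, peak, timepoint) log intensity from the model
#' documented in [effectSpec()] with i.i.d. Gaussian noise and returns
#' intensities on the linear scale, `exp(log-intensity)`. Identical
#' `(design, effects, seed)` yield bit-identical studies.
#'
#' @param design a [studyDesign()].
#' @param effects an [effectSpec()] with matching `nPeaks` and models.
#' @param seed RNG seed; defaults to the design's seed.
#' @return a \linkS4class{VocStudy}; ground-truth planted peak sets are
#'   available via [plantedDifferential()] and [plantedInteraction()].
#' @examples
#' study <- simulateStudy(studyDesign(nPerGroup = 5, nPeaks = 10, seed = 7))
#' study
#' @export
simulateStudy <- function(design = studyDesign(),
                          effects = effectSpec(design$nPeaks,
                                               design$models),
                          seed = design$seed) {
  if (!inherits(design, "StudyDesign")) vpConfigError("design must be a StudyDesign")
  if (!inherits(effects, "EffectSpec")) vpConfigError("effects must be an EffectSpec")
  if (effects$nPeaks != design$nPeaks)
    vpConfigError("design has %d peaks but effects specify %d",
                  design$nPeaks, effects$nPeaks)
  if (!identical(effects$models, design$models))
    vpConfigError("design and effects disagree on tumor models")

  p <- design$nPeaks
  peaks <- sprintf("P%02d", seq_len(p))
  grid <- expand.grid(sample = seq_len(design$nPerGroup),
                      timepoint = c("early", "late"),
                      condition = design$conditions,
                      model = design$models,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_%02d", grid$model, grid$condition,
                            grid$sample)
  nCol <- nrow(grid)

  logI <- withSeed(seed, {
    m <- matrix(rnorm(p * nCol, sd = effects$sigma), nrow = p, ncol = nCol)
    for (j in seq_len(nCol)) {
      shift <- effects$mu
      if (grid$timepoint[j] == "late") {
        shift <- shift + effects$tau
        if (grid$condition[j] == "tumor")
          shift <- shift + effects$delta + effects$gamma[, grid$model[j]]
      }
      m[, j] <- m[, j] + shift
    }
    m
  })
  dimnames(logI) <- list(peaks, paste(grid$sample_id, grid$timepoint,
                                      sep = "_"))

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = exp(logI)),
    colData = S4Vectors::DataFrame(sample_id = grid$sample_id,
                                   model = grid$model,
                                   condition = grid$condition,
                                   timepoint = grid$timepoint,
                                   row.names = colnames(logI)),
    metadata = list(design = design, effects = effects,
                    seed = as.integer(seed),
                    truth = list(
                      differential = peaks[effects$differentialPeaks],
                      interaction = peaks[effects$interactionPeaks])))
  methods::new("VocStudy", se)
}

#' Synthesize a total ion chromatogram as Gaussian peaks over a baseline
#'
#' Intensity at retention time t is
#' `baseline + sum_p height_p * exp(-(t - rt_p)^2 / (2 width_p^2))` plus
#' optional i.i.d. Gaussian noise. Overlapping (even identical) retention
#' times are allowed; the signals add.
#'
#' @param heights,centers,widths per-peak apex height, retention-time center
#'   (minutes) and Gaussian sd (minutes); equal lengths, possibly zero peaks.
#' @param grid strictly increasing retention-time grid (minutes).
#' @param baseline constant baseline level.
#' @param noiseSd sd of additive Gaussian noise (0 = noise-free).
#' @param seed RNG seed for the noise; ignored when `noiseSd = 0`.
#' @return a data.frame with columns `rt` and `intensity`.
#' @examples
#' tic <- simulateTic(10, 5, 0.1, grid = seq(0, 10, by = 0.01))
#' max(tic$intensity)
#' @export
simulateTic <- function(heights, centers, widths, grid, baseline = 0,
                        noiseSd = 0, seed = NULL) {
  if (!length(grid)) vpDataError("retention-time grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE))
    vpDataError("retention-time grid must be strictly increasing")
  np <- length(heights)
  if (length(centers) != np || length(widths) != np)
    vpConfigError("heights, centers and widths must have equal length")
  if (np && any(widths <= 0)) vpConfigError("peak widths must be positive")
  if (noiseSd < 0) vpConfigError("noiseSd must be >= 0")
  y <- rep(baseline, length(grid))
  for (i in seq_len(np))
    y <- y + heights[i] * exp(-(grid - centers[i])^2 / (2 * widths[i]^2))
  if (noiseSd > 0)
    y <- y + withSeed(seed, rnorm(length(grid), sd = noiseSd))
  data.frame(rt = grid, intensity = y)
}

#' Raw chromatograms for every measurement of a study
#'
#' Renders each column of a study's intensity matrix as a synthetic TIC with
#' one Gaussian peak per quantified peak, for exercising the chromatogram
#' stage end to end.
#'
#' @param study a \linkS4class{VocStudy}.
#' @param retentionTimes per-peak centers (minutes); default an even spacing
#'   wide enough that neighbouring peaks do not interfere.
#' @param widths per-peak Gaussian sd (minutes).
#' @param grid retention-time grid; default covers all peaks.
#' @param baseline,noiseSd,seed as in [simulateTic()]; per-sample noise seeds
#'   are derived deterministically from `seed`.
#' @return named list of TIC data.frames, one per study column.
#' @export
simulateStudyTics <- function(study, retentionTimes = NULL, widths = 0.05,
                              grid = NULL, baseline = 0, noiseSd = 0,
                              seed = 1L) {
  stopifnot(is(study, "VocStudy"))
  x <- intensities(study)
  p <- nrow(x)
  if (is.null(retentionTimes)) retentionTimes <- 2 + 0.8 * seq_len(p)
  widths <- rep_len(widths, p)
  if (is.null(grid))
    grid <- seq(max(0, min(retentionTimes) - 1),
                max(retentionTimes) + 1, by = 0.01)
  out <- lapply(seq_len(ncol(x)), function(j)
    simulateTic(x[, j], retentionTimes, widths, grid, baseline, noiseSd,
                seed = if (noiseSd > 0) seed + j else NULL))
  names(out) <- colnames(x)
  out
}

#' Flank tumor volume from caliper diameters
#'
#' `3.14 * largest * perpendicular^2 / 6`, with the coefficient 3.14 as used
#' in the flank-tumor protocol (not `pi`).
#'
#' @param largestDiameter,perpendicularDiameter caliper diameters in mm;
#'   non-negative, vectorized.
#' @return volume in mm^3.
#' @examples
#' tumorVolume(10, 5)
#' @export
tumorVolume <- function(largestDiameter, perpendicularDiameter) {
  if (any(largestDiameter < 0) || any(perpendicularDiameter < 0))
    vpConfigError("diameters must be non-negative")
  3.14 * largestDiameter * perpendicularDiameter^2 / 6
}

#' Fitted cubic tumor-growth curves for the two flank models
#'
#' Evaluates the cubic growth fit of the chosen tumor model at the given day
#' post injection: LKR `0.092 x^3 - 2.8 x^2 + 38 x - 18`; LLC
#' `0.16 x^3 - 0.83 x^2 + 3.5 x - 4`. Used only to scale synthetic early/late
#' effect magnitudes, not to simulate per-day samples.
#'
#' @param model `"LKR"` or `"LLC"`.
#' @param day day(s) post injection.
#' @return fitted volume(s).
#' @examples
#' growthCurve("LKR", 10)
#' @export
growthCurve <- function(model = c("LKR", "LLC"), day) {
  model <- tryCatch(match.arg(model),
                    error = function(e) vpConfigError(
                      "unknown tumor model '%s' (use LKR or LLC)",
                      paste(model, collapse = "/")))
  cf <- switch(model,
               LKR = c(0.092, -2.8, 38, -18),
               LLC = c(0.16, -0.83, 3.5, -4))
  cf[1] * day^3 + cf[2] * day^2 + cf[3] * day + cf[4]
}
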