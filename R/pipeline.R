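# End-to-end pipeline: simulate/ingest -> (optional) chromatogram
# quantification -> subtraction/normalization -> screening -> ANOVA ->
# PCA/SVM -> panel search, with every artifact written as CSV and the full
# configuration echoed.

#' Pipeline configuration
#'
#' Collects all thresholds, classifier settings, protocol sizes, mode flags
#' and seeds of a pipeline run; every persisted report echoes this
#' configuration.
#'
#' @param outDir directory for report CSVs (created if needed).
#' @param seed master seed; drives simulation, fold plans and hold-out splits.
#' @param models,nPerGroup,nPeaks study design (ignored when
#'   `inputPeakTable` is given).
#' @param effects optional [effectSpec()] override for simulation.
#' @param inputPeakTable optional CSV path; when given the study is read
#'   rather than simulated.
#' @param simulateTics also exercise the chromatogram stage: render each
#'   measurement as a raw TIC, re-detect windows and re-quantify.
#' @param offset log-transform offset.
#' @param alpha univariate screening threshold (default 1e-4).
#' @param screenMethod `"welch"`, `"pooled"` or `"wilcoxon"`.
#' @param anovaLoose,anovaStrict interaction screening thresholds.
#' @param sigma,C,tol RBF-SVM settings (sigma defaults to 0.9).
#' @param cvK cross-validation folds.
#' @param nTrain,nTest hold-out split per class.
#' @param pooledMode pooled (leaky) preprocessing, as the original analysis
#'   appears to have used; leak-free per-fold preprocessing is the default.
#' @param pcaComponents score-space dimension for the PCA+SVM stage.
#' @param panelProtocol `"cv10"` or `"holdout"` for the panel search.
#' @param maxPanelCandidates cap on screened candidates fed to the search.
#' @param runPanelSearch set `FALSE` to skip the (heaviest) search stage.
#' @return a validated `RunConfig` list.
#' @export
runConfig <- function(outDir = tempfile("vocpanel_run_"), seed = 1,
                      models = c("A", "B"), nPerGroup = 25, nPeaks = 47,
                      effects = NULL, inputPeakTable = NULL,
                      simulateTics = FALSE, offset = 1, alpha = 1e-4,
                      screenMethod = "welch", anovaLoose = 0.05,
                      anovaStrict = 0.002, sigma = 0.9, C = 1, tol = 1e-4,
                      cvK = 10, nTrain = 13, nTest = 12, pooledMode = FALSE,
                      pcaComponents = 2, panelProtocol = "cv10",
                      maxPanelCandidates = 11, runPanelSearch = TRUE) {
  chk01 <- function(v, nm) if (v <= 0 || v >= 1)
    vpConfigError("%s must be in (0, 1), got %s", nm, format(v))
  chk01(alpha, "alpha"); chk01(anovaLoose, "anovaLoose")
  chk01(anovaStrict, "anovaStrict")
  if (anovaStrict > anovaLoose)
    vpConfigError("anovaStrict must not exceed anovaLoose")
  if (cvK < 2) vpConfigError("cvK must be >= 2")
  if (sigma <= 0 || C <= 0) vpConfigError("sigma and C must be > 0")
  if (!panelProtocol %in% c("cv10", "holdout"))
    vpConfigError("panelProtocol must be 'cv10' or 'holdout'")
  structure(list(outDir = outDir, seed = seed, models = models,
                 nPerGroup = nPerGroup, nPeaks = nPeaks, effects = effects,
                 inputPeakTable = inputPeakTable,
                 simulateTics = simulateTics, offset = offset, alpha = alpha,
                 screenMethod = screenMethod, anovaLoose = anovaLoose,
                 anovaStrict = anovaStrict, sigma = sigma, C = C, tol = tol,
                 cvK = cvK, nTrain = nTrain, nTest = nTest,
                 pooledMode = pooledMode, pcaComponents = pcaComponents,
                 panelProtocol = panelProtocol,
                 maxPanelCandidates = maxPanelCandidates,
                 runPanelSearch = runPanelSearch),
            class = "RunConfig")
}

stageRun <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    e$message <- sprintf("stage '%s': %s", name, conditionMessage(e))
    stop(e)
  })
}

#' PCA score-space classification of one analysis set
#'
#' The descriptive two-dimensional analysis: project the normalized
#' subtracted values onto the leading principal components, train the RBF SVM
#' on the scores, and report the confusion metrics of the classified samples.
#'
#' @param R a normalized \linkS4class{SubtractedMatrix} with condition
#'   labels.
#' @param nComponents score-space dimension (default 2).
#' @param sigma,C,tol see [svmTrain()].
#' @return list with the `PcaModel`, the scores, the fitted `RbfSvm`,
#'   `confusionMetrics` of the training set, and the ROC-space point.
#' @export
scoreSpaceClassify <- function(R, nComponents = 2, sigma = 0.9, C = 1,
                               tol = 1e-4) {
  stopifnot(is(R, "SubtractedMatrix"))
  if (!length(R@condition)) vpDataError("R carries no condition labels")
  pca <- pcaFit(R@values)
  scores <- pcaProject(pca, R@values, k = nComponents)
  fit <- svmTrain(scores, R@condition, sigma = sigma, C = C, tol = tol)
  pred <- svmPredict(fit, scores)
  m <- confusionMetrics(pred$label, labelsToPM(R@condition))
  list(pca = pca, scores = scores, svm = fit, metrics = m,
       roc = rocPoint(m))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, optional chromatogram quantification, term-effect
#' subtraction and normalization, univariate screening, two-way ANOVA
#' interaction screening, PCA/SVM score-space classification, and the
#' exhaustive panel search; writes each stage's report CSV plus a JSON echo of
#' the configuration to `config$outDir`. Identical configurations produce
#' byte-identical report bodies. Any stage error aborts the run naming the
#' stage.
#'
#' @param config a [runConfig()].
#' @return the report bundle (study, per-model screening/classification/
#'   search, ANOVA table, transfer results, file paths), invisibly.
#' @examples
#' cfg <- runConfig(nPerGroup = 8, nPeaks = 10, runPanelSearch = FALSE,
#'                  cvK = 4)
#' bundle <- runPipeline(cfg)
#' names(bundle)
#' @export
runPipeline <- function(config = runConfig()) {
  if (!inherits(config, "RunConfig")) vpConfigError("config must be a RunConfig")
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  files <- character(0)

  study <- stageRun("ingest", {
    if (!is.null(config$inputPeakTable)) readPeakTable(config$inputPeakTable)
    else {
      des <- studyDesign(config$models, config$nPerGroup, config$nPeaks,
                         seed = config$seed)
      simulateStudy(des, effects = if (is.null(config$effects))
        effectSpec(des$nPeaks, des$models) else config$effects)
    }
  })
  writePeakTable(study, out("peak_table.csv"))
  files <- c(files, out("peak_table.csv"))
  if (!is.null(plantedDifferential(study))) {
    writeGroundTruth(study, out("ground_truth.csv"))
    files <- c(files, out("ground_truth.csv"))
  }

  if (config$simulateTics) {
    study <- stageRun("chromatogram", {
      tics <- simulateStudyTics(study, seed = config$seed)
      win <- detectPeakWindows(tics)
      if (nrow(win) != nrow(study))
        vpDataError("detected %d windows for %d peaks", nrow(win),
                    nrow(study))
      q <- t(quantifyTics(tics, win))  # peaks x measurements
      dimnames(q) <- dimnames(intensities(study))
      SummarizedExperiment::assay(study, "intensity") <- q
      study
    })
  }

  mods <- sort(unique(sampleInfo(study)$model))
  perModel <- list()
  for (m in mods) {
    res <- stageRun(paste0("features:", m), {
      R <- subtractTermEffect(study, tumorModel = m, offset = config$offset)
      Rn <- normalizeSubtracted(R)
      scr <- screenPeaks(Rn, alpha = config$alpha,
                         method = config$screenMethod)
      list(R = R, Rn = Rn, screening = scr)
    })
    write.csv(res$screening, out(sprintf("screening_%s.csv", m)),
              row.names = FALSE)
    files <- c(files, out(sprintf("screening_%s.csv", m)))
    perModel[[m]] <- res
  }

  anovaTab <- stageRun("anova", {
    twoWayAnova(pooledSubtracted(study, offset = config$offset),
                loose = config$anovaLoose, strict = config$anovaStrict)
  })
  write.csv(anovaTab, out("anova.csv"), row.names = FALSE)
  files <- c(files, out("anova.csv"))

  for (m in mods) {
    cls <- stageRun(paste0("classify:", m),
                    scoreSpaceClassify(perModel[[m]]$Rn,
                                       nComponents = config$pcaComponents,
                                       sigma = config$sigma, C = config$C,
                                       tol = config$tol))
    mm <- cls$metrics
    write.csv(data.frame(model = m, tp = mm$tp, fn = mm$fn, tn = mm$tn,
                         fp = mm$fp, sensitivity = mm$sensitivity,
                         specificity = mm$specificity,
                         accuracy = mm$accuracy, errorRate = mm$errorRate,
                         fpr = cls$roc[["fpr"]], tpr = cls$roc[["tpr"]]),
              out(sprintf("classify_%s.csv", m)), row.names = FALSE)
    files <- c(files, out(sprintf("classify_%s.csv", m)))
    perModel[[m]]$classify <- cls
  }

  if (config$runPanelSearch) {
    for (m in mods) {
      sr <- stageRun(paste0("panel_search:", m), {
        cand <- selectedPeaks(perModel[[m]]$screening)
        if (length(cand) > config$maxPanelCandidates)
          cand <- cand[seq_len(config$maxPanelCandidates)]
        if (length(cand) < 1L) NULL
        else exhaustiveSearch(subtractedValues(perModel[[m]]$R),
                              sampleConditions(perModel[[m]]$R),
                              candidates = cand,
                              protocol = config$panelProtocol,
                              k = config$cvK, seed = config$seed,
                              nTrain = config$nTrain, nTest = config$nTest,
                              sigma = config$sigma, C = config$C,
                              tol = config$tol,
                              pooledMode = config$pooledMode)
      })
      if (!is.null(sr)) {
        write.csv(sr$results, out(sprintf("panels_%s.csv", m)),
                  row.names = FALSE)
        files <- c(files, out(sprintf("panels_%s.csv", m)))
      }
      perModel[[m]]$search <- sr
    }

    # cross-model transfer of each model's top panel
    if (length(mods) == 2L) {
      transfer <- stageRun("transfer", {
        rows <- list()
        for (i in 1:2) {
          trainM <- mods[i]; testM <- mods[3 - i]
          sr <- perModel[[trainM]]$search
          if (is.null(sr)) next
          panel <- sr$best[[1L]]
          tr <- perModel[[trainM]]$R
          te <- perModel[[testM]]$R
          pr <- transferEval(subtractedValues(tr), sampleConditions(tr),
                             subtractedValues(te), sampleConditions(te),
                             subset = panel, sigma = config$sigma,
                             C = config$C, tol = config$tol)
          rows[[length(rows) + 1L]] <- data.frame(
            train = trainM, test = testM,
            panel = paste(panel, collapse = "+"),
            accuracy = pr$accuracy[["mean"]],
            sensitivity = pr$sensitivity[["mean"]],
            specificity = pr$specificity[["mean"]])
        }
        if (length(rows)) do.call(rbind, rows) else NULL
      })
      if (!is.null(transfer)) {
        write.csv(transfer, out("transfer.csv"), row.names = FALSE)
        files <- c(files, out("transfer.csv"))
      }
    } else transfer <- NULL
  } else transfer <- NULL

  echo <- config
  echo$effects <- if (is.null(config$effects)) "default" else "custom"
  jsonlite::write_json(unclass(echo), out("config.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  files <- c(files, out("config.json"))

  invisible(list(study = study, perModel = perModel, anova = anovaTab,
                 interaction = interactionScreen(anovaTab,
                                                 config$anovaLoose,
                                                 config$anovaStrict),
                 transfer = transfer, config = config, files = files))
}
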