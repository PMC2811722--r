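# Evaluation engine: per-class k-fold plans, exhaustive subset enumeration,
# cross-validation / hold-out / cross-model transfer protocols, and ranked
# panel search.

meanSem <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(c(mean = NA_real_, sem = NA_real_))
  c(mean = mean(v), sem = if (length(v) < 2L) 0 else sd(v) / sqrt(length(v)))
}

# kernel + SMO + sign prediction without S4 overhead; shared by every
# evaluation protocol so public and search results agree exactly
fitPredict <- function(xtr, ytr, xte, sigma, C, tol) {
  K <- .rbfKernelCpp(xtr, xtr, sigma)
  fit <- .smoTrainCpp(K, ytr, C, tol, 1000000L)
  f <- drop(.rbfKernelCpp(xte, xtr, sigma) %*% (fit$alpha * ytr)) + fit$b
  lab <- sign(f)
  lab[lab == 0] <- 1
  list(label = lab, decision = f)
}

foldMetrics <- function(predicted, truth) {
  m <- confusionMetrics(predicted, truth)
  c(ac = m$accuracy, se = m$sensitivity, sp = m$specificity)
}

summarizePanel <- function(perRep, panel, protocol, seed) {
  ac <- meanSem(100 * perRep[, "ac"])
  se <- meanSem(100 * perRep[, "se"])
  sp <- meanSem(100 * perRep[, "sp"])
  structure(list(panel = panel, protocol = protocol, seed = seed,
                 accuracy = ac, sensitivity = se, specificity = sp,
                 roc = c(fpr = 1 - sp[["mean"]] / 100,
                         tpr = se[["mean"]] / 100),
                 perReplicate = as.data.frame(perRep)),
            class = "PanelResult")
}

#' @export
print.PanelResult <- function(x, ...) {
  cat(sprintf("PanelResult [%s]: %s\n", x$protocol,
              paste(x$panel, collapse = ", ")))
  cat(sprintf("  accuracy %.2f +/- %.2f | sensitivity %.2f +/- %.2f | specificity %.2f +/- %.2f (percent)\n",
              x$accuracy[["mean"]], x$accuracy[["sem"]],
              x$sensitivity[["mean"]], x$sensitivity[["sem"]],
              x$specificity[["mean"]], x$specificity[["sem"]]))
  invisible(x)
}

#' Random per-class fold plan for k-fold cross-validation
#'
#' Partitions each class's samples into `k` folds of near-equal size (for 25
#' samples and k = 10: five folds of 3 and five of 2, matching sub-samples of
#' 1-3 animals). Fold j of one class is always tested together with fold j of
#' the other, so test sets contain both classes.
#'
#' @param y two-class labels, one per sample.
#' @param k number of folds; every class must have at least `k` samples.
#' @param seed RNG seed; equal seeds give identical plans.
#' @return a `FoldPlan`: per class, a list of `k` disjoint index vectors
#'   covering that class.
#' @examples
#' plan <- makeFolds(rep(c("tumor", "placebo"), each = 25), k = 10, seed = 1)
#' lengths(plan$classes$tumor)
#' @export
makeFolds <- function(y, k = 10, seed = 1) {
  f <- droplevels(as.factor(y))
  if (nlevels(f) != 2L) vpDataError("need exactly two classes")
  if (k < 2L) vpConfigError("k must be >= 2")
  classes <- withSeed(seed, {
    out <- list()
    for (lv in levels(f)) {
      ids <- which(f == lv)
      n <- length(ids)
      if (n < k)
        vpDataError("class '%s' has %d samples, fewer than k = %d", lv, n, k)
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      perm <- sample(ids)
      out[[lv]] <- split(perm, rep(seq_len(k), times = sizes))
    }
    out
  })
  structure(list(classes = classes, k = as.integer(k), seed = seed,
                 n = length(f)), class = "FoldPlan")
}

#' @export
print.FoldPlan <- function(x, ...) {
  cat(sprintf("FoldPlan: k=%d, seed=%s\n", x$k, format(x$seed)))
  for (lv in names(x$classes))
    cat(sprintf("  %s: fold sizes %s\n", lv,
                paste(lengths(x$classes[[lv]]), collapse = " ")))
  invisible(x)
}

#' All non-empty subsets of a peak list
#'
#' Enumerates the `2^p - 1` combinations without repetition in deterministic
#' lexicographic order (for peaks a, b, c: a; a,b; a,b,c; a,c; b; b,c; c).
#'
#' @param peaks vector of peak identifiers.
#' @return list of subsets (vectors in input order).
#' @examples
#' length(enumerateSubsets(paste0("P", 1:11)))  # 2047
#' @export
enumerateSubsets <- function(peaks) {
  p <- length(peaks)
  if (!p) vpConfigError("need at least one peak")
  out <- vector("list", 2^p - 1)
  pos <- 0L
  rec <- function(prefix, from) {
    for (i in from:p) {
      sub <- c(prefix, peaks[i])
      pos <<- pos + 1L
      out[[pos]] <<- sub
      if (i < p) rec(sub, i + 1L)
    }
  }
  rec(peaks[0], 1L)
  out
}

resolveSubset <- function(X, subset) {
  if (is.null(subset)) return(seq_len(ncol(X)))
  if (is.character(subset)) {
    idx <- match(subset, colnames(X))
    if (anyNA(idx))
      vpDataError("unknown peak(s): %s",
                  paste(subset[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(subset)
}

#' Evaluate a peak panel by k-fold cross-validation
#'
#' For each fold, the classifier is trained on the other k-1 folds of both
#' classes and tested on the held-out fold; per-fold accuracy, sensitivity and
#' specificity are averaged (mean and SEM = sd/sqrt(k), in percent). By
#' default feature centering/scaling is fit on the training folds only; the
#' `pooledMode` switch scales once on the pooled data, as the original analysis
#' appears to have projected all samples together. A test fold lacking one
#' class contributes no value to that class's rate (noted via `message`),
#' never a 0.
#'
#' @param X samples x peaks matrix (e.g. [subtractedValues()]).
#' @param y two-class labels per sample (tumor = positive).
#' @param subset peak names or column indices to use; default all.
#' @param folds a [makeFolds()] plan; built from `k` and `seed` when missing.
#' @param k,seed fold plan parameters when `folds` is missing.
#' @param sigma,C,tol classifier settings, see [svmTrain()].
#' @param standardize z-score features (leak-free unless `pooledMode`).
#' @param pooledMode fit scaling on the pooled data instead of per fold.
#' @return a `PanelResult` with per-fold metrics and their mean/SEM.
#' @export
crossValidate <- function(X, y, subset = NULL, folds = NULL, k = 10,
                          seed = 1, sigma = 0.9, C = 1, tol = 1e-4,
                          standardize = TRUE, pooledMode = FALSE) {
  X <- as.matrix(X)
  pm <- labelsToPM(y)
  if (is.null(folds)) folds <- makeFolds(y, k = k, seed = seed)
  idx <- resolveSubset(X, subset)
  Xs <- X[, idx, drop = FALSE]
  if (standardize && pooledMode) Xs <- applyScaler(Xs, fitScaler(Xs))
  kf <- folds$k
  perFold <- matrix(NA_real_, kf, 3L, dimnames = list(NULL, c("ac", "se", "sp")))
  for (j in seq_len(kf)) {
    te <- sort(unlist(lapply(folds$classes, `[[`, j), use.names = FALSE))
    tr <- setdiff(seq_len(nrow(Xs)), te)
    xtr <- Xs[tr, , drop = FALSE]
    xte <- Xs[te, , drop = FALSE]
    if (standardize && !pooledMode) {
      sc <- fitScaler(xtr)
      xtr <- applyScaler(xtr, sc)
      xte <- applyScaler(xte, sc)
    }
    pred <- fitPredict(xtr, pm[tr], xte, sigma, C, tol)
    perFold[j, ] <- foldMetrics(pred$label, pm[te])
  }
  if (anyNA(perFold[, c("se", "sp")]))
    message("some folds lacked a class; undefined rates excluded from the mean")
  summarizePanel(perFold, colnames(Xs), "cv10", folds$seed)
}

#' Evaluate a peak panel on random train/test hold-out splits
#'
#' Per seed, each class is split into `nTrain` training and `nTest` held-out
#' samples (13/12 for the 25-animal groups); metrics are computed on the test
#' set and summarized across seeds as mean and SEM (percent).
#'
#' @inheritParams crossValidate
#' @param nTrain,nTest per-class split sizes; classes smaller than
#'   `nTrain + nTest` are an error.
#' @param seeds one seed per replicate split.
#' @return a `PanelResult` (protocol `"holdout"`).
#' @export
holdoutEval <- function(X, y, subset = NULL, nTrain = 13, nTest = 12,
                        seeds = 1, sigma = 0.9, C = 1, tol = 1e-4,
                        standardize = TRUE, pooledMode = FALSE) {
  X <- as.matrix(X)
  pm <- labelsToPM(y)
  idx <- resolveSubset(X, subset)
  Xs <- X[, idx, drop = FALSE]
  if (standardize && pooledMode) Xs <- applyScaler(Xs, fitScaler(Xs))
  byClass <- split(seq_along(pm), pm)
  short <- vapply(byClass, length, 1L) < nTrain + nTest
  if (any(short))
    vpDataError("class size below the requested %d + %d split",
                nTrain, nTest)
  perRep <- matrix(NA_real_, length(seeds), 3L,
                   dimnames = list(NULL, c("ac", "se", "sp")))
  for (r in seq_along(seeds)) {
    parts <- withSeed(seeds[r], lapply(byClass, function(ids) {
      tr <- sample(ids, nTrain)
      rest <- setdiff(ids, tr)
      te <- if (length(rest) > nTest) sample(rest, nTest) else rest
      list(tr = tr, te = te)
    }))
    tr <- sort(unlist(lapply(parts, `[[`, "tr"), use.names = FALSE))
    te <- sort(unlist(lapply(parts, `[[`, "te"), use.names = FALSE))
    xtr <- Xs[tr, , drop = FALSE]
    xte <- Xs[te, , drop = FALSE]
    if (standardize && !pooledMode) {
      sc <- fitScaler(xtr)
      xtr <- applyScaler(xtr, sc)
      xte <- applyScaler(xte, sc)
    }
    pred <- fitPredict(xtr, pm[tr], xte, sigma, C, tol)
    perRep[r, ] <- foldMetrics(pred$label, pm[te])
  }
  summarizePanel(perRep, colnames(Xs), "holdout", seeds)
}

#' Evaluate a peak panel across tumor models (transfer)
#'
#' Trains on every sample of one tumor model and tests on every sample of the
#' other; normalization is fitted on the training model and applied to the
#' test model. Both datasets must share the peak vocabulary.
#'
#' @param trainX,trainY training-model data and labels.
#' @param testX,testY test-model data and labels.
#' @inheritParams crossValidate
#' @return a `PanelResult` (protocol `"transfer"`, single replicate).
#' @export
transferEval <- function(trainX, trainY, testX, testY, subset = NULL,
                         sigma = 0.9, C = 1, tol = 1e-4,
                         standardize = TRUE) {
  trainX <- as.matrix(trainX)
  testX <- as.matrix(testX)
  if (!is.null(colnames(trainX)) || !is.null(colnames(testX))) {
    if (!setequal(colnames(trainX), colnames(testX)))
      vpDataError("training and test data do not share the peak vocabulary")
    testX <- testX[, colnames(trainX), drop = FALSE]
  } else if (ncol(trainX) != ncol(testX)) {
    vpDataError("training and test data differ in peak count")
  }
  idx <- resolveSubset(trainX, subset)
  xtr <- trainX[, idx, drop = FALSE]
  xte <- testX[, idx, drop = FALSE]
  if (standardize) {
    sc <- fitScaler(xtr)
    xtr <- applyScaler(xtr, sc)
    xte <- applyScaler(xte, sc)
  }
  pred <- fitPredict(xtr, labelsToPM(trainY), xte, sigma, C, tol)
  perRep <- matrix(foldMetrics(pred$label, labelsToPM(testY)), 1L, 3L,
                   dimnames = list(NULL, c("ac", "se", "sp")))
  summarizePanel(perRep, colnames(xtr), "transfer", NA)
}

#' Exhaustive peak-panel search
#'
#' Evaluates every non-empty subset of the candidate peaks (2047 panels for
#' 11 candidates) under the chosen protocol and ranks panels by mean accuracy
#' (descending), then subset size (ascending), then mean sensitivity
#' (descending), then lexicographic panel identity.
#'
#' @inheritParams crossValidate
#' @param candidates peak names (or indices) to enumerate; more than
#'   `maxCandidates` is refused unless `force = TRUE` because the subset
#'   count doubles per peak.
#' @param protocol `"cv10"` (k-fold cross-validation, one fold plan shared by
#'   all panels) or `"holdout"` (random `nTrain`/`nTest` splits shared by all
#'   panels).
#' @param seeds replicate seeds for the hold-out protocol; defaults to `seed`.
#' @param nTrain,nTest hold-out split sizes per class.
#' @param maxCandidates,force guard against combinatorial blow-up.
#' @return object of class `PanelSearch`: `results` (ranked data.frame, one
#'   row per panel with mean/SEM metrics in percent and the ROC-space point)
#'   and `best` (all panels tying the top mean accuracy).
#' @examples
#' study <- simulateStudy(studyDesign(nPerGroup = 12, nPeaks = 6, seed = 5))
#' R <- subtractTermEffect(study, tumorModel = "A")
#' sr <- exhaustiveSearch(subtractedValues(R), sampleConditions(R),
#'                        candidates = peakIds(R)[1:4], k = 4)
#' head(sr$results)
#' @export
exhaustiveSearch <- function(X, y, candidates = colnames(X),
                             protocol = c("cv10", "holdout"), folds = NULL,
                             k = 10, seed = 1, seeds = NULL, nTrain = 13,
                             nTest = 12, sigma = 0.9, C = 1, tol = 1e-4,
                             standardize = TRUE, pooledMode = FALSE,
                             maxCandidates = 20, force = FALSE) {
  protocol <- match.arg(protocol)
  X <- as.matrix(X)
  pm <- labelsToPM(y)
  if (is.numeric(candidates) && is.null(colnames(X)))
    colnames(X) <- sprintf("P%02d", seq_len(ncol(X)))
  cand <- if (is.character(candidates)) candidates
          else colnames(X)[as.integer(candidates)]
  bad <- setdiff(cand, colnames(X))
  if (length(bad))
    vpDataError("unknown candidate peak(s): %s", paste(bad, collapse = ", "))
  cand <- sort(unique(cand))  # lexicographic enumeration order
  if (length(cand) > maxCandidates && !force)
    vpConfigError(paste("%d candidates imply 2^%d - 1 = %s subsets;",
                        "reduce the candidate list (e.g. screen first)",
                        "or set force = TRUE"),
                  length(cand), length(cand),
                  format(2^length(cand) - 1, big.mark = ","))

  Xc <- X[, cand, drop = FALSE]
  subsets <- enumerateSubsets(cand)

  # precompute train/test row sets and (leak-free) standardized copies of the
  # full candidate matrix, shared by all subsets
  if (protocol == "cv10") {
    if (is.null(folds)) folds <- makeFolds(y, k = k, seed = seed)
    reps <- lapply(seq_len(folds$k), function(j) {
      te <- sort(unlist(lapply(folds$classes, `[[`, j), use.names = FALSE))
      list(tr = setdiff(seq_len(nrow(Xc)), te), te = te)
    })
  } else {
    if (is.null(seeds)) seeds <- seed
    byClass <- split(seq_along(pm), pm)
    if (any(vapply(byClass, length, 1L) < nTrain + nTest))
      vpDataError("class size below the requested %d + %d split",
                  nTrain, nTest)
    reps <- lapply(seeds, function(s) {
      sp <- withSeed(s, lapply(byClass, function(ids) {
        tr <- sample(ids, nTrain)
        rest <- setdiff(ids, tr)
        te <- if (length(rest) > nTest) sample(rest, nTest) else rest
        list(tr = tr, te = te)
      }))
      list(tr = sort(unlist(lapply(sp, `[[`, "tr"), use.names = FALSE)),
           te = sort(unlist(lapply(sp, `[[`, "te"), use.names = FALSE)))
    })
  }
  if (standardize && pooledMode) Xc <- applyScaler(Xc, fitScaler(Xc))
  scaled <- lapply(reps, function(r) {
    if (standardize && !pooledMode) {
      sc <- fitScaler(Xc[r$tr, , drop = FALSE])
      applyScaler(Xc, sc)
    } else Xc
  })

  nRep <- length(reps)
  nSub <- length(subsets)
  acc <- se <- sp <- accS <- seS <- spS <- numeric(nSub)
  cols <- lapply(subsets, function(s) match(s, cand))
  for (i in seq_len(nSub)) {
    ci <- cols[[i]]
    perRep <- matrix(NA_real_, nRep, 3L)
    for (j in seq_len(nRep)) {
      r <- reps[[j]]
      Z <- scaled[[j]]
      pred <- fitPredict(Z[r$tr, ci, drop = FALSE], pm[r$tr],
                         Z[r$te, ci, drop = FALSE], sigma, C, tol)
      perRep[j, ] <- foldMetrics(pred$label, pm[r$te])
    }
    a <- meanSem(100 * perRep[, 1L]); acc[i] <- a[1L]; accS[i] <- a[2L]
    a <- meanSem(100 * perRep[, 2L]); se[i] <- a[1L]; seS[i] <- a[2L]
    a <- meanSem(100 * perRep[, 3L]); sp[i] <- a[1L]; spS[i] <- a[2L]
  }

  tab <- data.frame(
    panel = vapply(subsets, paste, "", collapse = "+"),
    size = lengths(subsets),
    accuracy = acc, accuracySem = accS,
    sensitivity = se, sensitivitySem = seS,
    specificity = sp, specificitySem = spS,
    fpr = 1 - sp / 100, tpr = se / 100)
  ord <- order(-tab$accuracy, tab$size, -tab$sensitivity, seq_len(nSub))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(results = tab,
                 best = subsets[ord][tab$accuracy == tab$accuracy[1L]],
                 protocol = protocol, candidates = cand,
                 sigma = sigma, C = C,
                 seed = if (protocol == "cv10") folds$seed else seeds),
            class = "PanelSearch")
}

#' @export
print.PanelSearch <- function(x, ...) {
  cat(sprintf("PanelSearch [%s]: %d candidates, %d panels evaluated\n",
              x$protocol, length(x$candidates), nrow(x$results)))
  cat("top panels:\n")
  print(utils::head(x$results, 5), row.names = FALSE)
  invisible(x)
}
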