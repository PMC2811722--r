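# Confusion-matrix metrics and the ROC-space coordinates used to report
# classifier panels.

#' Confusion-matrix metrics for a two-class prediction
#'
#' Counts true/false positives and negatives and reports
#' `se = tp / (tp + fn)`, `sp = tn / (tn + fp)`,
#' `ac = (tp + tn) / (tp + fp + tn + fn)` and `errorRate = 1 - ac`.
#' A ratio whose class is absent from the truth is reported as `NA`
#' (missing), not 0.
#'
#' @param predicted,truth equal-length label vectors (-1/+1 or two-level
#'   factors; `tumor` or the second level is the positive class).
#' @return list of class `confusionMetrics` with counts and rates.
#' @examples
#' m <- confusionMetrics(c(1, 1, -1, -1), c(1, -1, -1, -1))
#' m$accuracy
#' @export
confusionMetrics <- function(predicted, truth) {
  if (length(predicted) != length(truth) || !length(truth))
    vpDataError("predicted and truth must have equal, non-zero length")
  if (is.numeric(predicted) != is.numeric(truth))
    vpDataError("predicted and truth must use the same label coding")
  lev <- if (is.numeric(truth)) NULL else
    sort(unique(c(as.character(predicted), as.character(truth))))
  p <- labelsToPM2(predicted, lev)
  t <- labelsToPM2(truth, lev)
  tp <- sum(p > 0 & t > 0)
  tn <- sum(p < 0 & t < 0)
  fp <- sum(p > 0 & t < 0)
  fn <- sum(p < 0 & t > 0)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ac <- (tp + tn) / (tp + fp + tn + fn)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = se, specificity = sp, accuracy = ac,
                 errorRate = 1 - ac, misclassified = fp + fn),
            class = "confusionMetrics")
}

# like labelsToPM but tolerant of single-class vectors, with the level set
# shared between predicted and truth
labelsToPM2 <- function(y, lev = NULL) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) vpDataError("numeric labels must be -1/+1")
    return(as.numeric(y))
  }
  if (is.null(lev)) lev <- sort(unique(as.character(y)))
  if (length(lev) > 2L)
    vpDataError("more than two classes: %s", paste(lev, collapse = ", "))
  pos <- if ("tumor" %in% lev) "tumor" else lev[length(lev)]
  ifelse(as.character(y) == pos, 1, -1)
}

#' Build metrics directly from confusion counts
#'
#' @param tp,fn,tn,fp confusion-matrix counts.
#' @return as [confusionMetrics()].
#' @examples
#' countMetrics(tp = 22, fn = 3, tn = 25, fp = 0)  # se 0.88, sp 1, ac 0.94
#' @export
countMetrics <- function(tp, fn, tn, fp) {
  confusionMetrics(c(rep(1, tp), rep(-1, fn), rep(-1, tn), rep(1, fp)),
                   c(rep(1, tp + fn), rep(-1, tn + fp)))
}

#' @export
print.confusionMetrics <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fn=%d tn=%d fp=%d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.4g | specificity %.4g | accuracy %.4g | error rate %.4g\n",
              x$sensitivity, x$specificity, x$accuracy, x$errorRate))
  invisible(x)
}

#' ROC-space coordinates of a classifier
#'
#' @param metrics a `confusionMetrics` object.
#' @return named vector `(fpr, tpr) = (1 - specificity, sensitivity)`.
#' @export
rocPoint <- function(metrics) {
  c(fpr = 1 - metrics$specificity, tpr = metrics$sensitivity)
}
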