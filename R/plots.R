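# Optional figures (ggplot2, Suggests-only).

needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    vpConfigError("plotting requires the ggplot2 package")
}

#' Scatter plot of PCA scores colored by group
#'
#' @param scores samples x 2 score matrix (e.g. from [scoreSpaceClassify()]).
#' @param labels group label per sample.
#' @return a ggplot object.
#' @export
plotScores <- function(scores, labels) {
  needGgplot()
  df <- data.frame(PC1 = scores[, 1L], PC2 = scores[, 2L],
                   group = as.factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group,
                                   shape = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_bw()
}

#' ROC-space scatter of panel-search results
#'
#' Plots every evaluated panel at (1 - specificity, sensitivity), sized by
#' panel size.
#'
#' @param search a `PanelSearch` (from [exhaustiveSearch()]) or its `results`
#'   data.frame.
#' @return a ggplot object.
#' @export
plotRocSpace <- function(search) {
  needGgplot()
  df <- if (inherits(search, "PanelSearch")) search$results else search
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   size = .data$size)) +
    ggplot2::geom_point(alpha = 0.4, colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate (1 - specificity)",
                  y = "true positive rate (sensitivity)") +
    ggplot2::theme_bw()
}
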