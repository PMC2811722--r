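# PCA projection used for the two-dimensional score-space classification.

#' Fit a linear PCA model
#'
#' Centers features by their training means and takes components from the
#' covariance eigendecomposition (via [stats::prcomp()]); no scaling. The sign
#' of each loading vector is fixed so that its largest-magnitude entry is
#' positive, making fits reproducible.
#'
#' @param x samples x features matrix, at least 2 samples and 1 feature.
#' @return a \linkS4class{PcaModel}.
#' @examples
#' m <- pcaFit(matrix(rnorm(40), 10))
#' m@varExplained
#' @export
pcaFit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 1L)
    vpDataError("PCA needs at least 2 samples and 1 feature")
  if (!all(is.finite(x))) vpDataError("PCA input must be finite")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  varTot <- sum(pc$sdev^2)
  methods::new("PcaModel", center = pc$center, rotation = rot,
               sdev = pc$sdev,
               varExplained = if (varTot > 0) pc$sdev^2 / varTot
                              else rep(0, length(pc$sdev)))
}

#' Project samples onto the leading principal components
#'
#' @param model a \linkS4class{PcaModel}.
#' @param x samples x features matrix on the same features as the fit.
#' @param k number of leading components (default 2, the score plane used for
#'   the classifier); must not exceed the fitted rank.
#' @return samples x k score matrix; the training mean projects to the zero
#'   vector.
#' @export
pcaProject <- function(model, x, k = 2) {
  stopifnot(is(model, "PcaModel"))
  x <- as.matrix(x)
  rank <- sum(model@sdev > max(model@sdev) * 1e-12)
  if (k > ncol(model@rotation) || k > rank)
    vpConfigError("k = %d exceeds the fitted rank (%d)", k, rank)
  if (ncol(x) != nrow(model@rotation))
    vpDataError("feature count (%d) does not match the fit (%d)",
                ncol(x), nrow(model@rotation))
  sweep(x, 2L, model@center, "-") %*% model@rotation[, seq_len(k), drop = FALSE]
}
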