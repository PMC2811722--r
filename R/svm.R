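# Soft-margin Gaussian-kernel SVM. Training solves the C-SVM dual
#   max  sum(alpha) - 1/2 sum alpha_i alpha_j y_i y_j k(x_i, x_j)
#   s.t. 0 <= alpha <= C, sum alpha_i y_i = 0
# by sequential minimal optimization with second-order working-set selection
# (compiled, src/smo.cpp). k(x, x') = exp(-sigma ||x - x'||^2).

#' Gaussian (RBF) kernel matrix
#'
#' `k(x, x') = exp(-sigma * ||x - x'||^2)`; `sigma` multiplies the squared
#' distance (the kernlab `rbfdot` convention, under which the study's
#' parameter value 0.9 is interpreted).
#'
#' @param x,x2 samples x features matrices (rows are points); `x2` defaults
#'   to `x`.
#' @param sigma positive kernel parameter.
#' @return `nrow(x)` x `nrow(x2)` kernel matrix.
#' @export
rbfKernel <- function(x, x2 = x, sigma = 0.9) {
  if (sigma <= 0) vpConfigError("sigma must be > 0")
  .rbfKernelCpp(as.matrix(x), as.matrix(x2), sigma)
}

#' Train a soft-margin RBF support vector machine
#'
#' Maximizes the margin between the two classes in the kernel-induced feature
#' space, allowing violations at cost `C` per unit slack. The dual problem is
#' solved to KKT tolerance `tol`; the decision function is
#' `f(x) = sum_s alpha_s y_s k(x_s, x) + b` and samples are classified by its
#' sign.
#'
#' @param x samples x features matrix with finite entries.
#' @param y labels: numeric -1/+1 or a two-level factor (`tumor`, or
#'   otherwise the second level, is coded +1). Both classes must be present.
#' @param sigma kernel parameter (default 0.9, the study's setting).
#' @param C soft-margin penalty (default 1; the study does not state a
#'   value).
#' @param tol KKT violation at which the solver stops.
#' @param maxIter iteration cap for the SMO solver.
#' @return an \linkS4class{RbfSvm}.
#' @examples
#' x <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
#' fit <- svmTrain(x, rep(c(-1, 1), each = 10), C = 10)
#' fit
#' @export
svmTrain <- function(x, y, sigma = 0.9, C = 1, tol = 1e-4, maxIter = 1e6) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) vpDataError("features must be finite")
  pm <- labelsToPM(y)
  if (length(pm) != nrow(x)) vpDataError("labels must match the sample count")
  if (length(unique(pm)) < 2L)
    vpDataError("training data contain a single class")
  if (sigma <= 0 || C <= 0) vpConfigError("sigma and C must be > 0")

  K <- .rbfKernelCpp(x, x, sigma)
  fit <- .smoTrainCpp(K, pm, C, tol, as.integer(maxIter))
  sv <- which(fit$alpha > 1e-9)
  methods::new("RbfSvm", sigma = sigma, cost = C,
               svX = x[sv, , drop = FALSE], svY = pm[sv],
               svAlpha = fit$alpha[sv], b = fit$b,
               objective = fit$objective, gap = fit$gap, tol = tol,
               iterations = as.integer(fit$iterations),
               nTrain = nrow(x), positiveLabel = attr(pm, "positive"))
}

#' Predict with a fitted RBF SVM
#'
#' Deterministic: labels are the sign of the decision value; an exact zero is
#' assigned to the positive class with a warning.
#'
#' @param model an \linkS4class{RbfSvm}.
#' @param x samples x features matrix (possibly 0 rows).
#' @return list with `label` (-1/+1) and `decision` vectors.
#' @export
svmPredict <- function(model, x) {
  stopifnot(is(model, "RbfSvm"))
  x <- as.matrix(x)
  if (nrow(x) == 0L)
    return(list(label = numeric(0), decision = numeric(0)))
  if (ncol(x) != ncol(model@svX))
    vpDataError("feature count (%d) does not match the model (%d)",
                ncol(x), ncol(model@svX))
  f <- drop(.rbfKernelCpp(x, model@svX, model@sigma) %*%
              (model@svAlpha * model@svY)) + model@b
  lab <- sign(f)
  if (any(lab == 0)) {
    warning("decision value exactly 0; assigning the positive class",
            call. = FALSE)
    lab[lab == 0] <- 1
  }
  list(label = lab, decision = f)
}

#' @describeIn svmPredict standard `predict` interface; returns labels, or
#'   decision values with `type = "decision"`.
#' @param object an \linkS4class{RbfSvm}.
#' @param type `"label"` or `"decision"`.
#' @param ... unused.
#' @export
setMethod("predict", "RbfSvm",
          function(object, x, type = c("label", "decision"), ...) {
  type <- match.arg(type)
  out <- svmPredict(object, x)
  if (type == "label") out$label else out$decision
})

#' Platt-style class probabilities from decision values
#'
#' Fits a logistic sigmoid `P(+1 | f) = 1 / (1 + exp(A f + B))` to training
#' decision values, for coloring score-space backgrounds by class
#' probability. Purely cosmetic; no pipeline decision uses it.
#'
#' @param decision training decision values.
#' @param y training labels (-1/+1 or two-level factor).
#' @return a function mapping decision values to positive-class
#'   probabilities.
#' @export
plattScale <- function(decision, y) {
  pm <- labelsToPM(y)
  fit <- glm((pm + 1) / 2 ~ decision, family = binomial())
  a <- coef(fit)
  function(f) 1 / (1 + exp(-(a[1L] + a[2L] * f)))
}
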