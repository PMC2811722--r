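# PCA projection, RBF-SVM training/prediction, confusion metrics.

test_that("PCA on collinear data explains everything with one component", {
  t <- seq(-2, 2, length.out = 9)
  x <- cbind(t, 2 * t)
  m <- pcaFit(x)
  expect_equal(m@varExplained[1], 1)
  # the training mean projects to the origin
  expect_equal(unname(pcaProject(m, matrix(colMeans(x), 1), k = 1)[1, 1]), 0)
})

test_that("PCA matches the covariance eigendecomposition and reconstructs", {
  set.seed(2)
  x <- matrix(rnorm(15), 5, 3)
  m <- pcaFit(x)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  for (j in 1:3) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(m@rotation[, j]), unname(v), tolerance = 1e-8)
  }
  scores <- pcaProject(m, x, k = 3)
  # scores are decorrelated across components
  cp <- crossprod(scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  # full reconstruction of the centered data
  rec <- scores %*% t(m@rotation[, 1:3])
  expect_equal(rec, sweep(x, 2, colMeans(x)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcaProject(m, x, k = 4), class = "vocpanel_config_error")
})

test_that("kernel identities hold: unit diagonal, symmetry, PSD", {
  set.seed(3)
  x <- matrix(rnorm(24), 8, 3)
  K <- rbfKernel(x, sigma = 0.9)
  expect_equal(diag(K), rep(1, 8))
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  expect_error(rbfKernel(x, sigma = 0), class = "vocpanel_config_error")
})

test_that("well-separated clouds are classified perfectly", {
  d <- makeClouds(n = 10, sep = 6, seed = 4)
  fit <- svmTrain(d$x, d$y, sigma = 0.9, C = 10)
  pred <- svmPredict(fit, d$x)
  expect_equal(pred$label, d$y)
})

test_that("the RBF machine separates XOR data where no linear rule can", {
  d <- makeXor(m = 8, seed = 5)
  fit <- svmTrain(d$x, d$y, sigma = 0.9, C = 10)
  expect_equal(svmPredict(fit, d$x)$label, d$y)  # training accuracy 1
  expect_lt(bestLinearAccuracy(d$x, d$y), 1)     # a hyperplane cannot do this
})

test_that("KKT conditions hold at the solution", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 16
    x <- matrix(rnorm(2 * n), n)
    y <- rep(c(-1, 1), each = n / 2)
    C <- c(0.5, 1, 5, 10, 2)[rep]
    fit <- svmTrain(x, y, sigma = 0.9, C = C, tol = 1e-8)
    f <- svmPredict(fit, x)$decision
    alpha <- rep(0, n)
    # recover full alpha from stored support vectors by matching rows
    key <- apply(x, 1, paste, collapse = ",")
    skey <- apply(fit@svX, 1, paste, collapse = ",")
    alpha[match(skey, key)] <- fit@svAlpha
    expect_lt(abs(sum(alpha * y)), 1e-6)
    margin <- alpha > 1e-6 & alpha < C - 1e-6
    if (any(margin))
      expect_lt(max(abs(y[margin] * f[margin] - 1)), 1e-3)
    expect_true(all(y[alpha < 1e-6] * f[alpha < 1e-6] >= 1 - 1e-3))
    expect_true(all(y[alpha > C - 1e-6] * f[alpha > C - 1e-6] <= 1 + 1e-3))
  }
})

test_that("the dual solution matches an independent QP solver", {
  skip_if_not_installed("kernlab")
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(10:20, 1)
    x <- matrix(rnorm(2 * n), n)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- runif(1, 0.5, 5)
    fit <- svmTrain(x, y, sigma = 0.9, C = C, tol = 1e-10)
    K <- rbfKernel(x, sigma = 0.9)
    H <- K * (y %o% y)
    qp <- kernlab::ipop(c = rep(-1, n), H = H + diag(1e-12, n), A = t(y),
                        b = 0, l = rep(0, n), u = rep(C, n), r = 0,
                        sigf = 12, maxiter = 400)
    a <- kernlab::primal(qp)
    oracleObj <- sum(a) - 0.5 * drop(t(a) %*% H %*% a)
    expect_equal(fit@objective, oracleObj, tolerance = 1e-6)
  }
})

test_that("prediction is symmetric under label swap and handles empty input", {
  d <- makeClouds(n = 6, sep = 2, seed = 8)
  f1 <- svmTrain(d$x, d$y, C = 2, tol = 1e-8)
  f2 <- svmTrain(d$x, -d$y, C = 2, tol = 1e-8)
  expect_equal(svmPredict(f1, d$x)$decision,
               -svmPredict(f2, d$x)$decision, tolerance = 1e-6)
  empty <- svmPredict(f1, d$x[0, , drop = FALSE])
  expect_length(empty$label, 0)
  expect_length(empty$decision, 0)
})

test_that("degenerate SVM inputs are rejected", {
  x <- matrix(rnorm(10), 5)
  expect_error(svmTrain(x, rep(1, 5)), class = "vocpanel_data_error")
  x[1] <- NA
  expect_error(svmTrain(x, c(1, 1, -1, -1, 1)),
               class = "vocpanel_data_error")
  expect_error(svmTrain(matrix(rnorm(8), 4), c(1, 1, -1, -1), C = -1),
               class = "vocpanel_config_error")
})

test_that("confusion metrics reproduce the two worked test-set examples", {
  # 25 tumor + 25 placebo, 3 misses as false negatives
  lkr <- countMetrics(tp = 22, fn = 3, tn = 25, fp = 0)
  expect_equal(lkr$sensitivity, 0.88)
  expect_equal(lkr$specificity, 1.00)
  expect_equal(lkr$accuracy, 0.94)
  expect_equal(lkr$misclassified, 3)
  # 3 misses as false positives
  llc <- countMetrics(tp = 25, fp = 3, tn = 22, fn = 0)
  expect_equal(llc$sensitivity, 1.00)
  expect_equal(llc$specificity, 0.88)
  expect_equal(llc$accuracy, 0.94)
  expect_equal(llc$misclassified, 3)
  expect_equal(rocPoint(lkr), c(fpr = 0, tpr = 0.88))
})

test_that("metrics identities hold on random confusion tables", {
  set.seed(9)
  for (i in 1:20) {
    cnt <- sample(0:30, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    m <- countMetrics(tp = cnt[1], fn = cnt[2], tn = cnt[3], fp = cnt[4])
    P <- cnt[1] + cnt[2]
    N <- cnt[3] + cnt[4]
    if (P > 0 && N > 0)
      expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
    expect_equal(m$errorRate, 1 - m$accuracy)
  }
  perfect <- confusionMetrics(c(1, -1), c(1, -1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$errorRate, 0)
  expect_equal(rocPoint(perfect), c(fpr = 0, tpr = 1))
  # all-positive predictor on balanced data sits at (1, 1)
  allPos <- confusionMetrics(rep(1, 10), rep(c(1, -1), 5))
  expect_equal(rocPoint(allPos), c(fpr = 1, tpr = 1))
  # empty truth class: the undefined rate is NA, not 0
  noPos <- confusionMetrics(rep(-1, 4), rep(-1, 4))
  expect_true(is.na(noPos$sensitivity))
  expect_equal(noPos$specificity, 1)
})

test_that("Platt scaling gives monotone probabilities", {
  d <- makeClouds(n = 15, sep = 3, seed = 10)
  fit <- svmTrain(d$x, d$y, C = 1)
  f <- svmPredict(fit, d$x)$decision
  prob <- plattScale(f, d$y)
  g <- seq(min(f), max(f), length.out = 20)
  expect_true(all(diff(prob(g)) > 0))
  expect_true(all(prob(g) > 0 & prob(g) < 1))
})

test_that("score-space classification separates a strong synthetic study", {
  study <- simulateStudy(studyDesign(nPerGroup = 15, nPeaks = 20, seed = 12))
  Rn <- normalizeSubtracted(subtractTermEffect(study, tumorModel = "A"))
  cls <- scoreSpaceClassify(Rn, nComponents = 2)
  expect_gte(cls$metrics$accuracy, 0.8)
  expect_identical(dim(cls$scores), c(30L, 2L))
})
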