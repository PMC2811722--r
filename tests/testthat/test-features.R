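mk <- function(v, n = 4, p = 3) {
  m <- matrix(v, n, p)
  dimnames(m) <- list(sprintf("s%d", 1:n), sprintf("P%02d", 1:p))
  m
}

test_that("subtraction is late minus early, with identity special cases", {
  e <- mk(rnorm(12))
  expect_equal(subtractedValues(subtractTermEffect(e, e)), e - e)
  z <- mk(0)
  l <- mk(rnorm(12))
  expect_equal(subtractedValues(subtractTermEffect(z, l)), l)
  expect_false(isNormalized(subtractTermEffect(z, l)))
})

test_that("sample/peak mismatches are rejected naming the offenders", {
  e <- mk(rnorm(12))
  l <- mk(rnorm(12))
  rownames(l)[2] <- "sX"
  expect_error(subtractTermEffect(e, l), "sX",
               class = "vocpanel_data_error")
  l <- mk(rnorm(12))
  colnames(l)[3] <- "P99"
  expect_error(subtractTermEffect(e, l), "P99",
               class = "vocpanel_data_error")
})

test_that("repeated collections within a stage enter as per-sample maxima", {
  a <- mk(1)
  b <- mk(3)
  l <- mk(5)
  R <- subtractTermEffect(list(a, b), l)
  expect_equal(unname(subtractedValues(R)), unname(l - pmax(a, b)))
})

test_that("peak z-scoring matches the hand-computed population z-score", {
  m <- cbind(P1 = c(1, 2, 3), P2 = c(4, 4, 4))
  expect_warning(z <- normalizeSubtracted(m), "zero-variance")
  expect_equal(z[, "P1"], c(-1.2247, 0, 1.2247), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(unname(z[, "P2"]), c(0, 0, 0))
  # idempotent on non-degenerate columns
  m2 <- cbind(P1 = rnorm(10), P2 = rnorm(10))
  expect_equal(normalizeSubtracted(normalizeSubtracted(m2)),
               normalizeSubtracted(m2), tolerance = 1e-12)
})

test_that("subtract-then-normalize removes additive stage-wide shifts", {
  set.seed(1)
  e <- mk(rnorm(12))
  l <- mk(rnorm(12))
  base <- normalizeSubtracted(subtractTermEffect(e, l))
  # per-sample constant added to both stages cancels in the subtraction
  c_s <- rnorm(4)
  base2 <- normalizeSubtracted(subtractTermEffect(e + c_s, l + c_s))
  expect_equal(subtractedValues(base2), subtractedValues(base),
               tolerance = 1e-12)
  # per-peak term effect added to the late stage only is removed by centering
  tau <- rnorm(3)
  base3 <- normalizeSubtracted(
    subtractTermEffect(e, l + matrix(tau, 4, 3, byrow = TRUE)))
  expect_equal(subtractedValues(base3), subtractedValues(base),
               tolerance = 1e-12)
})

test_that("screening p-values agree with an independent Welch evaluation", {
  set.seed(7)
  x <- cbind(P01 = c(rnorm(25, 3), rnorm(25, 0)),
             P02 = rnorm(50))
  y <- rep(c("tumor", "placebo"), each = 25)
  rep <- screenPeaks(x, y, alpha = 1e-4)
  o <- welchOracle(x[1:25, "P01"], x[26:50, "P01"])
  r1 <- rep[rep$peak == "P01", ]
  expect_equal(r1$statistic, o$t, tolerance = 1e-10)
  expect_equal(r1$p, o$p, tolerance = 1e-10)
  expect_true(r1$p < 1e-4 && r1$selected)
  expect_false(rep$selected[rep$peak == "P02"])
  expect_identical(selectedPeaks(rep), "P01")
})

test_that("identical class distributions yield no selections", {
  x <- cbind(P01 = rep(c(1, 2, 3, 4, 5), 2))
  y <- rep(c("tumor", "placebo"), each = 5)
  rep <- screenPeaks(x, y, alpha = 1e-4)
  expect_false(any(rep$selected))
})

test_that("screening requires two adequately sized classes", {
  x <- mk(rnorm(12))
  expect_error(screenPeaks(x, c("tumor", "placebo", "tumor", "tumor")),
               class = "vocpanel_data_error")
  expect_error(screenPeaks(x, rep("tumor", 4)), class = "vocpanel_data_error")
})

test_that("false-positive rate under the global null matches alpha in expectation", {
  alpha <- 0.05
  rates <- vapply(1:30, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(20 * 20), 20, dimnames = list(NULL, sprintf("P%02d", 1:20)))
    y <- rep(c("tumor", "placebo"), each = 10)
    mean(screenPeaks(x, y, alpha = alpha)$selected)
  }, numeric(1))
  expect_gt(mean(rates), alpha / 2.5)
  expect_lt(mean(rates), alpha * 2.5)
})

test_that("alternative screening tests are available", {
  set.seed(3)
  x <- cbind(P01 = c(rnorm(15, 2), rnorm(15)))
  y <- rep(c("tumor", "placebo"), each = 15)
  pw <- screenPeaks(x, y, method = "wilcoxon", alpha = 0.01)
  pp <- screenPeaks(x, y, method = "pooled", alpha = 0.01)
  expect_true(pw$selected[1] && pp$selected[1])
})
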