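# Fold plans, subset enumeration, CV / hold-out / transfer protocols, and the
# exhaustive ranked search.

informativeData <- function(n = 25, pGood = 2, pNoise = 2, d = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("tumor", "placebo"), each = n)
  shift <- ifelse(y == "tumor", d / 2, -d / 2)
  x <- cbind(matrix(rnorm(2 * n * pGood) + shift, ncol = pGood),
             matrix(rnorm(2 * n * pNoise), ncol = pNoise))
  colnames(x) <- c(sprintf("G%02d", seq_len(pGood)),
                   sprintf("N%02d", seq_len(pNoise)))
  list(x = x, y = y)
}

test_that("fold plans partition each class into k near-equal folds", {
  y <- rep(c("tumor", "placebo"), each = 25)
  plan <- makeFolds(y, k = 10, seed = 1)
  for (cl in plan$classes) {
    sizes <- lengths(cl)
    expect_identical(length(cl), 10L)
    expect_true(all(sizes %in% 2:3))
    expect_identical(sum(sizes), 25L)
    ids <- unlist(cl)
    expect_identical(anyDuplicated(ids), 0L)
  }
  expect_setequal(unlist(plan$classes$tumor), which(y == "tumor"))
  # determinism and distinctness across seeds
  expect_identical(makeFolds(y, 10, seed = 7), makeFolds(y, 10, seed = 7))
  expect_false(identical(makeFolds(y, 10, 7), makeFolds(y, 10, 8)))
  # n = k gives singleton folds
  y10 <- rep(c("tumor", "placebo"), each = 10)
  expect_true(all(lengths(makeFolds(y10, 10, 1)$classes$tumor) == 1L))
  expect_error(makeFolds(rep(c("tumor", "placebo"), each = 5), k = 10),
               class = "vocpanel_data_error")
})

test_that("subset enumeration is complete and lexicographic", {
  s3 <- enumerateSubsets(c("a", "b", "c"))
  expect_identical(vapply(s3, paste, "", collapse = ""),
                   c("a", "ab", "abc", "ac", "b", "bc", "c"))
  expect_length(enumerateSubsets("x"), 1L)
  expect_length(enumerateSubsets(sprintf("P%02d", 1:11)), 2047L)
})

test_that("cross-validation scores a separable panel perfectly", {
  d <- informativeData(n = 20, d = 8, seed = 2)
  pr <- crossValidate(d$x, d$y, subset = c("G01", "G02"), k = 10, seed = 3)
  expect_equal(pr$accuracy[["mean"]], 100)
  expect_equal(pr$accuracy[["sem"]], 0)
  expect_equal(pr$roc, c(fpr = 0, tpr = 1))
  expect_identical(nrow(pr$perReplicate), 10L)
})

test_that("destroying the labels drives CV accuracy to chance", {
  d <- informativeData(n = 15, d = 3, seed = 4)
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    yPerm <- sample(d$y)
    crossValidate(d$x, yPerm, k = 5, seed = s)$accuracy[["mean"]]
  }, numeric(1))
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})

test_that("duplicating every sample does not degrade fold-mean accuracy", {
  # each sample's twin can land in the training folds, so the duplicated run
  # may only gain (memorization); on clearly separated data both are perfect
  diffs <- vapply(1:10, function(s) {
    d <- informativeData(n = 10, d = 2.5, seed = s)
    a1 <- crossValidate(d$x, d$y, k = 5, seed = s)$accuracy[["mean"]]
    a2 <- crossValidate(rbind(d$x, d$x), c(d$y, d$y), k = 5,
                        seed = s)$accuracy[["mean"]]
    a2 - a1
  }, numeric(1))
  expect_gt(mean(diffs), -5)
  sep <- informativeData(n = 10, d = 8, seed = 99)
  expect_equal(crossValidate(rbind(sep$x, sep$x), c(sep$y, sep$y), k = 5,
                             seed = 1)$accuracy[["mean"]], 100)
})

test_that("hold-out splits are exact and score separable data perfectly", {
  d <- informativeData(n = 25, d = 8, seed = 5)
  pr <- holdoutEval(d$x, d$y, subset = c("G01", "G02"), nTrain = 13,
                    nTest = 12, seeds = 1:3)
  expect_equal(pr$accuracy[["mean"]], 100)
  expect_identical(nrow(pr$perReplicate), 3L)
  expect_identical(13L + 12L, 25L)
  expect_error(holdoutEval(d$x[c(1:10, 26:35), ], d$y[c(1:10, 26:35)]),
               class = "vocpanel_data_error")
})

test_that("panels with planted peaks beat panels without them on hold-out", {
  wins <- vapply(1:10, function(s) {
    d <- informativeData(n = 25, pGood = 2, pNoise = 2, d = 2.5, seed = s)
    sr <- exhaustiveSearch(d$x, d$y, candidates = colnames(d$x),
                           protocol = "holdout", seeds = s + 100,
                           nTrain = 13, nTest = 12)
    tab <- sr$results
    both <- grepl("G01", tab$panel) & grepl("G02", tab$panel)
    neither <- !grepl("G01", tab$panel) & !grepl("G02", tab$panel)
    max(tab$accuracy[both]) >= max(tab$accuracy[neither])
  }, logical(1))
  expect_gte(sum(wins), 9L)
})

test_that("transfer to an identical test set reproduces training metrics", {
  d <- informativeData(n = 12, d = 3, seed = 6)
  pr <- transferEval(d$x, d$y, d$x, d$y)
  ctr <- colMeans(d$x)
  scl <- apply(d$x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  xs <- sweep(sweep(d$x, 2, ctr), 2, scl, "/")
  fit <- svmTrain(xs, d$y)
  m <- confusionMetrics(svmPredict(fit, xs)$label,
                        ifelse(d$y == "tumor", 1, -1))
  expect_equal(pr$accuracy[["mean"]], 100 * m$accuracy)
  expect_equal(pr$sensitivity[["mean"]], 100 * m$sensitivity)
  expect_equal(pr$specificity[["mean"]], 100 * m$specificity)
})

test_that("transfer succeeds when models share the signal and fails when not", {
  shared <- vapply(1:10, function(s) {
    a <- informativeData(n = 15, d = 3, seed = s)
    b <- informativeData(n = 15, d = 3, seed = s + 50)
    transferEval(a$x, a$y, b$x, b$y,
                 subset = c("G01", "G02"))$accuracy[["mean"]]
  }, numeric(1))
  expect_gte(mean(shared > 50), 0.9)

  # informative only in the training model; the panel carries no signal for
  # the test model, so transfer sits at chance
  disjoint <- vapply(1:10, function(s) {
    a <- informativeData(n = 15, pGood = 1, pNoise = 1, d = 3, seed = s)
    set.seed(s + 99)
    bx <- matrix(rnorm(30 * 2), 30,
                 dimnames = list(NULL, colnames(a$x)))
    by <- rep(c("tumor", "placebo"), each = 15)
    transferEval(a$x, a$y, bx, by, subset = "G01")$accuracy[["mean"]]
  }, numeric(1))
  expect_lt(abs(mean(disjoint) - 50), 20)
})

test_that("vocabulary mismatches between models are rejected", {
  a <- informativeData(n = 10, seed = 1)
  b <- informativeData(n = 10, seed = 2)
  colnames(b$x)[1] <- "ZZ"
  expect_error(transferEval(a$x, a$y, b$x, b$y),
               class = "vocpanel_data_error")
})

test_that("a perfectly separating singleton ranks first", {
  set.seed(11)
  n <- 20
  y <- rep(c("tumor", "placebo"), each = n)
  x <- cbind(PA = ifelse(y == "tumor", 10, -10) + rnorm(2 * n, sd = 0.1),
             PZ = rnorm(2 * n))
  sr <- exhaustiveSearch(x, y, candidates = c("PA", "PZ"), k = 5, seed = 1)
  expect_identical(sr$results$panel[1], "PA")
  expect_equal(sr$results$accuracy[1], 100)
})

test_that("ties are broken by size then lexicographic panel identity", {
  set.seed(12)
  n <- 20
  y <- rep(c("tumor", "placebo"), each = n)
  good <- ifelse(y == "tumor", 10, -10) + rnorm(2 * n, sd = 0.1)
  x <- cbind(PA = good, PB = good)  # PB duplicates the best peak
  sr <- exhaustiveSearch(x, y, candidates = c("PB", "PA"), k = 5, seed = 1)
  expect_equal(sr$results$accuracy, rep(100, 3))
  expect_identical(sr$results$panel[1], "PA")   # lexicographic first
  expect_identical(sr$results$size[1:3], c(1L, 1L, 2L))
})

test_that("pure-noise candidates stay inside the null band", {
  set.seed(13)
  x <- matrix(rnorm(40 * 4), 40,
              dimnames = list(NULL, sprintf("N%02d", 1:4)))
  y <- rep(c("tumor", "placebo"), each = 20)
  sr <- exhaustiveSearch(x, y, k = 5, seed = 2)
  expect_lt(sr$results$accuracy[1], 85)  # top of 15 noise panels
})

test_that("search bails out on too many candidates and one row per subset", {
  x <- matrix(rnorm(10 * 21), 10,
              dimnames = list(NULL, sprintf("C%02d", 1:21)))
  y <- rep(c("tumor", "placebo"), 5)
  expect_error(exhaustiveSearch(x, y), class = "vocpanel_config_error")
  d <- informativeData(n = 8, pGood = 1, pNoise = 2, seed = 3)
  sr <- exhaustiveSearch(d$x, d$y, k = 4, seed = 1)
  expect_identical(nrow(sr$results), 7L)
  expect_identical(anyDuplicated(sr$results$panel), 0L)
})
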