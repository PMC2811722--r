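# Shared fixtures, built in code.

# two Gaussian clouds separated along the first axis
makeClouds <- function(n = 10, sep = 4, p = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p, -sep / 2), n),
             matrix(rnorm(n * p, sep / 2), n))
  list(x = x, y = rep(c(-1, 1), each = n))
}

# XOR-patterned clusters: opposite corners share a label
makeXor <- function(m = 8, spread = 0.15, seed = 1) {
  set.seed(seed)
  ctr <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  x <- do.call(rbind, lapply(1:4, function(i)
    cbind(rnorm(m, ctr[i, 1], spread), rnorm(m, ctr[i, 2], spread))))
  list(x = x, y = rep(c(1, 1, -1, -1), each = m))
}

# best training accuracy of any linear classifier, by exhaustive angle sweep
bestLinearAccuracy <- function(x, y, nAngles = 720) {
  best <- 0
  for (a in seq(0, pi, length.out = nAngles)) {
    proj <- x %*% c(cos(a), sin(a))
    for (thr in sort(unique(proj))) {
      for (s in c(-1, 1)) {
        pred <- ifelse(s * (proj - thr) >= 0, 1, -1)
        best <- max(best, mean(pred == y))
      }
    }
  }
  best
}

# Welch two-sample t, written out from the textbook formula (independent of
# stats::t.test), with p from the t distribution
welchOracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# classical balanced two-way ANOVA via a least-squares fit (independent path)
lmAnovaOracle <- function(y, condition, model) {
  fit <- stats::lm(y ~ condition * model)
  tab <- stats::anova(fit)
  list(ss = tab$`Sum Sq`, f = tab$`F value`[1:3], p = tab$`Pr(>F)`[1:3])
}

# balanced 2x2 layout with standard-normal noise and optional cell means
make2x2 <- function(n = 25, cellMeans = c(0, 0, 0, 0), sd = 1, seed = 1) {
  set.seed(seed)
  condition <- factor(rep(c("tumor", "placebo"), each = 2 * n))
  model <- factor(rep(rep(c("A", "B"), each = n), 2))
  mu <- cellMeans[(as.integer(condition) - 1) * 2 + as.integer(model)]
  list(y = mu + rnorm(4 * n, sd = sd), condition = condition, model = model)
}

smallStudy <- function(seed = 1, nPerGroup = 10, nPeaks = 10, ...) {
  des <- studyDesign(nPerGroup = nPerGroup, nPeaks = nPeaks, seed = seed)
  simulateStudy(des, effects = effectSpec(nPeaks, des$models, ...))
}
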