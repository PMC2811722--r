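# internal helpers: error conditions, seeded evaluation, label coding

vpConfigError <- function(fmt, ...) {
  stop(structure(
    class = c("vocpanel_config_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

vpDataError <- function(fmt, ...) {
  stop(structure(
    class = c("vocpanel_data_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    vpConfigError("seed must be a single finite number, got %s",
                  deparse(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# population (1/n) standard deviation, the convention used for z-scoring
popSd <- function(x) sqrt(mean((x - mean(x))^2))

# Map two-class labels to {-1, +1}. "tumor"/"placebo" always codes tumor as
# +1; otherwise the second factor level is the positive class (as in glm).
labelsToPM <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1)))
      vpDataError("numeric labels must be -1/+1")
    return(structure(as.numeric(y), positive = "+1"))
  }
  f <- as.factor(y)
  lev <- levels(droplevels(f))
  if (length(lev) != 2L)
    vpDataError("expected exactly 2 classes, got %d (%s)",
                length(lev), paste(lev, collapse = ", "))
  pos <- if (all(c("tumor", "placebo") %in% lev)) "tumor" else lev[2L]
  structure(ifelse(as.character(f) == pos, 1, -1), positive = pos)
}

# center/scale columns by training statistics; zero-spread columns are
# centered only (scale treated as 1)
fitScaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, popSd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

applyScaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}
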