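# Chromatogram preprocessing: detect peak windows shared across all samples
# on the point-wise mean trace, quantify each window by its maximum height,
# then log-transform and correct per-sample overall intensity.

checkTic <- function(tic) {
  if (!is.data.frame(tic) || !all(c("rt", "intensity") %in% names(tic)))
    vpDataError("a TIC must be a data.frame with columns rt and intensity")
  if (!nrow(tic)) vpDataError("TIC has an empty retention-time grid")
  if (is.unsorted(tic$rt, strictly = TRUE))
    vpDataError("TIC retention-time grid must be strictly increasing")
  invisible(tic)
}

#' Detect peak windows shared across a set of chromatograms
#'
#' Components are detected simultaneously across all samples: the point-wise
#' mean trace is computed on the common retention-time grid, and every local
#' maximum whose height is at least `minProminence` times the mean-trace
#' maximum becomes a window center. Centers closer than `minSeparation`
#' minutes are merged (the higher one is kept). Each half-open window
#' `[start, end)` extends to the midpoint between adjacent centers - or, at
#' the flanks, `minSeparation` beyond the first/last center - and is clipped
#' to the grid range. Detection is fully deterministic.
#'
#' @param tics a TIC data.frame (columns `rt`, `intensity`) or a list of them
#'   on an identical grid; resample beforehand if grids differ.
#' @param minProminence height threshold as a fraction of the mean-trace
#'   maximum.
#' @param minSeparation minimum center separation in minutes.
#' @return data.frame with columns `window`, `center`, `start`, `end`;
#'   zero rows when no maximum exceeds the threshold.
#' @examples
#' tic <- simulateTic(c(5, 9), c(2, 4), c(0.1, 0.1), seq(0, 6, 0.01))
#' detectPeakWindows(tic)
#' @export
detectPeakWindows <- function(tics, minProminence = 0.01,
                              minSeparation = 0.2) {
  if (is.data.frame(tics)) tics <- list(tics)
  if (!length(tics)) vpDataError("need at least one chromatogram")
  lapply(tics, checkTic)
  rt <- tics[[1L]]$rt
  for (t in tics[-1L])
    if (!isTRUE(all.equal(t$rt, rt)))
      vpDataError("chromatograms are not on a common retention-time grid; resample first")
  if (minProminence <= 0 || minProminence > 1)
    vpConfigError("minProminence must be in (0, 1]")
  if (minSeparation <= 0) vpConfigError("minSeparation must be > 0")

  m <- rowMeans(vapply(tics, function(t) t$intensity, numeric(length(rt))))
  empty <- data.frame(window = character(0), center = numeric(0),
                      start = numeric(0), end = numeric(0))
  top <- max(m)
  if (!is.finite(top) || top <= 0) return(empty)
  thr <- minProminence * top

  n <- length(m)
  if (n < 3L) return(empty)
  isMax <- m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n] &
    m[2:(n - 1)] >= thr
  cand <- which(isMax) + 1L
  if (!length(cand)) return(empty)

  # keep the highest of any cluster of near-coincident maxima
  keep <- integer(0)
  for (i in cand[order(-m[cand], rt[cand])]) {
    if (!length(keep) || all(abs(rt[i] - rt[keep]) >= minSeparation))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  ctr <- rt[keep]
  k <- length(ctr)
  step <- rt[2L] - rt[1L]
  lo <- c(ctr[1L] - minSeparation,
          if (k > 1) (ctr[-k] + ctr[-1L]) / 2)
  hi <- c(if (k > 1) (ctr[-k] + ctr[-1L]) / 2,
          ctr[k] + minSeparation)
  lo <- pmax(lo, rt[1L])
  hi <- pmin(hi, rt[n] + step)  # half-open end just past the last grid point
  data.frame(window = sprintf("W%02d", seq_len(k)), center = ctr,
             start = lo, end = hi)
}

#' Quantify one chromatogram against a set of peak windows
#'
#' The height of each window is the maximum intensity among grid points in
#' the half-open interval `[start, end)`. A window containing no grid point
#' gets height 0 with a warning.
#'
#' @param tic TIC data.frame (columns `rt`, `intensity`).
#' @param windows data.frame as returned by [detectPeakWindows()].
#' @return named numeric vector of per-window heights.
#' @export
quantifyPeaks <- function(tic, windows) {
  checkTic(tic)
  h <- vapply(seq_len(nrow(windows)), function(i) {
    sel <- tic$rt >= windows$start[i] & tic$rt < windows$end[i]
    if (!any(sel)) {
      warning(sprintf("window %s contains no grid point; height set to 0",
                      windows$window[i]), call. = FALSE)
      return(0)
    }
    max(tic$intensity[sel])
  }, numeric(1))
  names(h) <- windows$window
  h
}

#' Quantify many chromatograms into a peak table
#'
#' @param tics named list of TIC data.frames (one per sample).
#' @param windows peak windows shared by all samples.
#' @return matrix, samples in rows and windows in columns.
#' @export
quantifyTics <- function(tics, windows) {
  if (!length(tics)) vpDataError("need at least one chromatogram")
  t(vapply(tics, quantifyPeaks, numeric(nrow(windows)), windows = windows))
}

#' Log-transform peak heights
#'
#' `value -> ln(value + offset)`; the default offset 1 keeps zero heights
#' finite and maps them to 0.
#'
#' @param x numeric matrix (samples x peaks) or vector.
#' @param offset non-negative constant added before taking logs.
#' @return object of the same shape.
#' @export
logTransform <- function(x, offset = 1) {
  if (offset < 0) vpConfigError("offset must be >= 0")
  if (any(x + offset <= 0))
    vpDataError("log transform undefined: values + offset must be positive")
  log(x + offset)
}

#' Correct per-sample overall intensity level
#'
#' Centers each sample (row) of a log-scale peak table by its own row mean,
#' the standard total-intensity correction; output rows have mean 0. The
#' operation is idempotent and invariant to adding a constant to any row.
#'
#' @param x numeric matrix, samples x peaks.
#' @return row-centered matrix.
#' @export
normalizeIntensity <- function(x) {
  x <- as.matrix(x)
  sweep(x, 1L, rowMeans(x), "-")
}
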