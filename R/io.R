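# CSV interchange: one long peak table (rows = sample-by-timepoint
# measurements, columns = metadata + peak identifiers), 2-column TIC traces,
# and a ground-truth sidecar. UTF-8, header row, '.' decimal.

metaCols <- c("sample_id", "model", "condition", "timepoint")

fmtNum <- function(x) sub("^\\s+", "", sprintf("%.17g", x))  # exact round-trip

#' Write a study's peak table to CSV
#'
#' One row per (animal, timepoint) measurement: the metadata columns
#' `sample_id`, `model`, `condition`, `timepoint` followed by one column per
#' peak with linear-scale intensities at full precision, so
#' `readPeakTable(writePeakTable(x))` reproduces `x` exactly.
#'
#' @param study a \linkS4class{VocStudy}.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(study, path) {
  stopifnot(is(study, "VocStudy"))
  cd <- sampleInfo(study)
  x <- t(intensities(study))
  df <- cbind(cd[, metaCols, drop = FALSE],
              as.data.frame(apply(x, 2L, fmtNum, simplify = FALSE),
                            check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak table CSV into a study object
#'
#' Validates the header (all metadata columns present, at least one peak
#' column), rejects duplicate sample measurements and duplicate peak columns,
#' and returns a \linkS4class{VocStudy}. Ground truth, if written alongside
#' by [writeGroundTruth()], is not re-attached automatically.
#'
#' @param path CSV written by [writePeakTable()] (or matching its layout).
#' @return a \linkS4class{VocStudy}.
#' @export
readPeakTable <- function(path) {
  if (!file.exists(path)) vpDataError("no such file: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) vpDataError("peak table is empty: %s", path)
  miss <- setdiff(metaCols, names(df))
  if (length(miss))
    vpDataError("missing metadata column(s): %s", paste(miss, collapse = ", "))
  peakCols <- setdiff(names(df), metaCols)
  if (!length(peakCols)) vpDataError("no peak columns found")
  if (anyDuplicated(peakCols))
    vpDataError("duplicate peak column(s): %s",
                paste(unique(peakCols[duplicated(peakCols)]), collapse = ", "))
  key <- paste(df$sample_id, df$timepoint)
  if (anyDuplicated(key))
    vpDataError("duplicate measurement row(s): %s",
                paste(unique(key[duplicated(key)]), collapse = ", "))
  m <- t(as.matrix(df[, peakCols, drop = FALSE]))
  mode(m) <- "numeric"
  if (anyNA(m)) vpDataError("non-numeric or missing intensities in %s", path)
  colnames(m) <- paste(df$sample_id, df$timepoint, sep = "_")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    colData = S4Vectors::DataFrame(df[, metaCols, drop = FALSE],
                                   row.names = colnames(m)))
  methods::new("VocStudy", se)
}

#' Write the planted ground-truth peak sets of a synthetic study
#'
#' @param study a simulated \linkS4class{VocStudy}.
#' @param path output CSV path (columns `peak`, `role`).
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(study, path) {
  stopifnot(is(study, "VocStudy"))
  d <- plantedDifferential(study)
  i <- plantedInteraction(study)
  write.csv(data.frame(peak = c(d, i),
                       role = c(rep("differential", length(d)),
                                rep("interaction", length(i)))),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a single TIC trace as a 2-column CSV
#'
#' @param tic data.frame with columns `rt`, `intensity`.
#' @param path CSV path.
#' @return `writeTic`: `path` invisibly; `readTic`: the TIC data.frame.
#' @export
writeTic <- function(tic, path) {
  checkTic(tic)
  write.csv(data.frame(rt = fmtNum(tic$rt),
                       intensity = fmtNum(tic$intensity)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTic
#' @export
readTic <- function(path) {
  if (!file.exists(path)) vpDataError("no such file: %s", path)
  df <- read.csv(path)
  if (!all(c("rt", "intensity") %in% names(df)))
    vpDataError("TIC CSV must have columns rt and intensity")
  checkTic(df[, c("rt", "intensity")])
}
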