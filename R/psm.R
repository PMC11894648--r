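# PSM tables use the MaxQuant msms.txt/evidence.txt column dialect
# directly as data.frame column names (check.names = FALSE):
#   "Reporter intensity <k>" / "Reporter intensity corrected <k>"
#   (1-based channel index in label-set order), "Precursor intensity",
#   "Ion injection time", "PIF", "Base peak ratio", "Proteins",
#   "Experiment", plus a plex identifier column (default "Plex").

.reporterCols <- function(n, corrected = FALSE) {
  paste0(if (corrected) "Reporter intensity corrected "
         else "Reporter intensity ", seq_len(n))
}

# number of channels = count of contiguous "Reporter intensity k" columns
.psmChannelCount <- function(psm, corrected = FALSE) {
  n <- 0L
  repeat {
    if (!(.reporterCols(n + 1L, corrected)[n + 1L] %in% names(psm))) break
    n <- n + 1L
  }
  n
}

.psmReporterMatrix <- function(psm, corrected = FALSE, n = NULL) {
  if (is.null(n)) n <- .psmChannelCount(psm, corrected)
  if (n == 0L)
    stop("no '", if (corrected) "Reporter intensity corrected"
         else "Reporter intensity", " <k>' columns found")
  as.matrix(psm[.reporterCols(n, corrected)])
}

.psmPlex <- function(psm, plexColumn = "Plex") {
  if (plexColumn %in% names(psm)) return(as.character(psm[[plexColumn]]))
  if ("Experiment" %in% names(psm)) return(as.character(psm$Experiment))
  stop("PSM table has neither a '", plexColumn,
       "' nor an 'Experiment' column")
}

#' Add impurity-corrected reporter columns to a PSM table
#'
#' Applies [correctImpurities()] to every spectrum's raw reporter vector
#' and stores the result in \code{Reporter intensity corrected <k>}
#' columns parallel to the raw ones, matching the MaxQuant output
#' dialect.
#'
#' @param psm PSM data.frame in the MaxQuant column dialect.
#' @param M a [MixingMatrix-class] whose label set matches the table's
#'   channel count.
#' @return the PSM table with corrected columns added (or replaced).
#' @export
correctPSMTable <- function(psm, M) {
  stopifnot(is(M, "MixingMatrix"))
  n <- nChannels(M@labelSet)
  Y <- .psmReporterMatrix(psm, corrected = FALSE)
  if (ncol(Y) != n)
    stop("PSM table has ", ncol(Y), " reporter channels but the mixing ",
         "matrix expects ", n)
  X <- correctImpurities(Y, M)
  psm[.reporterCols(n, corrected = TRUE)] <- as.data.frame(X)
  psm
}

#' Precursor intensity fraction of an isolation window
#'
#' PIF is the fraction of the summed peak intensity inside the isolation
#' window that belongs to the isotope peaks of the targeted precursor;
#' co-isolated background lowers it and causes ratio compression.
#'
#' @param precursorPeaks intensities of the precursor's own peaks.
#' @param windowPeaks intensities of all peaks in the isolation window
#'   (a superset of \code{precursorPeaks}).
#' @return PIF, clipped to [0, 1].
#' @examples
#' computePIF(90, c(90, 10))          # 0.9
#' computePIF(c(50, 30), c(50, 30, 20))  # 0.8
#' @export
computePIF <- function(precursorPeaks, windowPeaks) {
  if (length(windowPeaks) == 0L || sum(windowPeaks) <= 0)
    stop("empty isolation window")
  min(1, max(0, sum(precursorPeaks) / sum(windowPeaks)))
}

.thresholdFilter <- function(psm, column, threshold, what) {
  v <- psm[[column]]
  if (is.null(v)) {
    if (threshold > 0)
      stop("PSM table has no '", column, "' column; cannot apply a ",
           what, " threshold > 0")
    return(psm)
  }
  keep <- if (threshold == 0) is.na(v) | v >= threshold else
    !is.na(v) & v >= threshold
  psm[keep, , drop = FALSE]
}

#' Quantification filters on PSM tables
#'
#' [pifFilter()] keeps PSMs whose precursor intensity fraction is at
#' least \code{threshold}; [basePeakRatioFilter()] does the same for the
#' base peak ratio.  PSMs with a missing value pass only at threshold 0,
#' so the zero threshold is the identity filter.
#'
#' @param psm PSM data.frame.
#' @param threshold PIF threshold in [0, 1], base-peak-ratio
#'   threshold >= 0.
#' @return the filtered PSM table.
#' @export
pifFilter <- function(psm, threshold) {
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 1)
  .thresholdFilter(psm, "PIF", threshold, "PIF")
}

#' @rdname pifFilter
#' @export
basePeakRatioFilter <- function(psm, threshold) {
  stopifnot(length(threshold) == 1L, threshold >= 0)
  .thresholdFilter(psm, "Base peak ratio", threshold, "base peak ratio")
}
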