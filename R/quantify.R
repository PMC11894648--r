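#' Weighted-median normalization configuration
#'
#' @param mode \code{"all_sample_sum"}: ratios are taken to the sum of
#'   all sample channels of the PSM's plex (no reference channels
#'   needed); \code{"reference"}: ratios to the summed reference
#'   channel(s) of the plex.  Carrier and empty channels never
#'   contribute in either mode.
#' @param weightExponent the isobaric weight exponent applied to
#'   precursor intensity x fill time (0 = unweighted medians).
#' @param useCorrected use the impurity-corrected reporter columns.
#' @param minPSMs minimum number of surviving sample/reference ratios a
#'   cell needs; below it the cell is missing.
#' @param pifThreshold optional PIF threshold applied before
#'   normalization (NULL = no filter).
#' @return a validated configuration list of class \code{"WMConfig"}.
#' @export
wmConfig <- function(mode = c("all_sample_sum", "reference"),
                     weightExponent = 1, useCorrected = FALSE,
                     minPSMs = 1L, pifThreshold = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(weightExponent) == 1L, is.finite(weightExponent),
            weightExponent >= 0, length(minPSMs) == 1L, minPSMs >= 1)
  if (!is.null(pifThreshold))
    stopifnot(length(pifThreshold) == 1L, pifThreshold >= 0,
              pifThreshold <= 1)
  structure(list(mode = mode, weightExponent = weightExponent,
                 useCorrected = isTRUE(useCorrected),
                 minPSMs = as.integer(minPSMs),
                 pifThreshold = pifThreshold),
            class = "WMConfig")
}

#' Per-PSM reference intensity
#'
#' The denominator of the sample/reference ratios: in \code{"reference"}
#' mode the sum of the plex's reference channels, in
#' \code{"all_sample_sum"} mode the sum over all sample-role channels.
#' Carrier and empty channels are excluded in both modes.
#'
#' @param psm PSM data.frame.
#' @param design an [ExperimentalDesign-class].
#' @param mode \code{"reference"} or \code{"all_sample_sum"}.
#' @param useCorrected use corrected reporter columns.
#' @param plexColumn name of the plex identifier column.
#' @return numeric vector, one reference intensity per PSM row.
#' @export
referenceIntensity <- function(psm, design,
                               mode = c("all_sample_sum", "reference"),
                               useCorrected = FALSE, plexColumn = "Plex") {
  mode <- match.arg(mode)
  stopifnot(is(design, "ExperimentalDesign"))
  .checkReferenceChannels(design, mode)
  Y <- .psmReporterMatrix(psm, corrected = useCorrected,
                          n = nChannels(design))
  plex <- .psmPlex(psm, plexColumn)
  role <- if (mode == "reference") "reference" else "sample"
  out <- numeric(nrow(psm))
  for (p in unique(plex)) {
    idx <- .roleIndices(design, p, role)
    rows <- plex == p
    out[rows] <- rowSums(Y[rows, idx, drop = FALSE])
  }
  out
}

.checkReferenceChannels <- function(design, mode) {
  if (mode != "reference") return(invisible())
  for (p in plexNames(design))
    if (length(.roleIndices(design, p, "reference")) == 0L)
      stop("mode \"reference\" requires at least one reference channel ",
           "in every plex, but plex '", p, "' has none")
}

.quantMatrix <- function(values, counts, design, kind, config = NULL) {
  si <- sampleInfo(design)
  stopifnot(identical(colnames(values), rownames(si)))
  cd <- S4Vectors::DataFrame(sample = si$sample, plex = si$plex,
                             channel = si$channel, group = si$group,
                             row.names = si$sample)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(quant = values, nPSM = counts), colData = cd,
    metadata = list(kind = kind, config = config,
                    channels = channelNames(design@labelSet),
                    labelSet = design@labelSet@name))
  new("QuantMatrix", se)
}

#' @rdname QuantMatrix-class
#' @export
setMethod("quantValues", "QuantMatrix",
          function(x) SummarizedExperiment::assay(x, "quant"))

#' @rdname QuantMatrix-class
#' @export
setMethod("psmCounts", "QuantMatrix",
          function(x) SummarizedExperiment::assay(x, "nPSM"))

#' @rdname QuantMatrix-class
#' @export
setMethod("quantKind", "QuantMatrix",
          function(x) S4Vectors::metadata(x)$kind)

#' @export
setMethod("show", "QuantMatrix", function(object) {
  cat("QuantMatrix [", quantKind(object), "]: ", nrow(object),
      " protein groups x ", ncol(object), " samples\n", sep = "")
  cat("  missing cells: ", sum(is.na(quantValues(object))), "\n", sep = "")
  callNextMethod()
})

#' Summed (unnormalized) protein-group roll-up
#'
#' Per protein group and sample channel, the sum of reporter intensities
#' over all of that group's PSMs in the sample's plex.  Records from
#' multiple fractions sharing a plex/experiment identifier are summed
#' together.  A group with no surviving PSM in a plex gets missing
#' values there, not zeros.
#'
#' @param psm PSM data.frame (a \code{Proteins} column assigns each PSM
#'   to one protein group).
#' @param design an [ExperimentalDesign-class].
#' @param useCorrected sum the impurity-corrected reporter columns.
#' @param plexColumn name of the plex identifier column.
#' @return a [QuantMatrix-class] of kind \code{summed_raw} or
#'   \code{summed_corrected}.
#' @export
aggregateSum <- function(psm, design, useCorrected = FALSE,
                         plexColumn = "Plex") {
  stopifnot(is(design, "ExperimentalDesign"))
  if (is.null(psm$Proteins)) stop("PSM table has no 'Proteins' column")
  Y <- .psmReporterMatrix(psm, corrected = useCorrected,
                          n = nChannels(design))
  plex <- .psmPlex(psm, plexColumn)
  prot <- as.character(psm$Proteins)
  proteins <- sort(unique(prot))
  si <- sampleInfo(design)
  values <- matrix(NA_real_, length(proteins), nrow(si),
                   dimnames = list(proteins, rownames(si)))
  counts <- matrix(0L, length(proteins), nrow(si),
                   dimnames = dimnames(values))
  for (p in unique(plex)) {
    rows <- plex == p
    sp <- si[si$plex == p, , drop = FALSE]
    if (nrow(sp) == 0L) next
    idx <- match(sp$channel, channelNames(design@labelSet))
    sums <- rowsum(Y[rows, idx, drop = FALSE], prot[rows])
    npsm <- as.integer(table(prot[rows])[rownames(sums)])
    values[rownames(sums), rownames(sp)] <- sums
    counts[rownames(sums), rownames(sp)] <- npsm
  }
  .quantMatrix(values, counts, design,
               kind = if (useCorrected) "summed_corrected" else
                 "summed_raw",
               config = list(useCorrected = isTRUE(useCorrected)))
}

#' Weighted-median normalized protein-group quantification
#'
#' For each protein group and sample channel, collects over the group's
#' PSMs (in that sample's plex) the ratios of the sample channel
#' intensity to the PSM's reference intensity (see
#' [referenceIntensity()]), weights each ratio by
#' \code{(precursor intensity x fill time)^weightExponent}
#' ([psmWeight()]), and reports the weighted median of the ratios
#' ([weightedMedian()]).  PSMs with a zero sample or zero reference
#' intensity are skipped for that cell; a cell with fewer than
#' \code{minPSMs} surviving ratios is missing.  Because every ratio is
#' formed within one spectrum, any plex-wide intensity scale factor
#' cancels, which is what removes batch effects between plexes.
#'
#' @inheritParams aggregateSum
#' @param config a [wmConfig()] configuration.
#' @return a [QuantMatrix-class] of kind \code{wm_normalized} holding
#'   the weighted-median ratios.
#' @export
wmNormalize <- function(psm, design, config = wmConfig(),
                        plexColumn = "Plex") {
  stopifnot(is(design, "ExperimentalDesign"), inherits(config, "WMConfig"))
  .checkReferenceChannels(design, config$mode)
  if (is.null(psm$Proteins)) stop("PSM table has no 'Proteins' column")
  if (!is.null(config$pifThreshold))
    psm <- pifFilter(psm, config$pifThreshold)
  Y <- .psmReporterMatrix(psm, corrected = config$useCorrected,
                          n = nChannels(design))
  plex <- .psmPlex(psm, plexColumn)
  prot <- as.character(psm$Proteins)
  proteins <- sort(unique(prot))
  w <- psmWeight(psm[["Precursor intensity"]], psm[["Ion injection time"]],
                 config$weightExponent)
  si <- sampleInfo(design)
  values <- matrix(NA_real_, length(proteins), nrow(si),
                   dimnames = list(proteins, rownames(si)))
  counts <- matrix(0L, length(proteins), nrow(si),
                   dimnames = dimnames(values))
  refRole <- if (config$mode == "reference") "reference" else "sample"
  for (p in unique(plex)) {
    rows <- which(plex == p)
    if (!length(rows)) next
    sp <- si[si$plex == p, , drop = FALSE]
    if (nrow(sp) == 0L) next
    refIdx <- .roleIndices(design, p, refRole)
    ref <- rowSums(Y[rows, refIdx, drop = FALSE])
    for (s in rownames(sp)) {
      c_idx <- match(sp[s, "channel"], channelNames(design@labelSet))
      num <- Y[rows, c_idx]
      ok <- num > 0 & ref > 0
      if (!any(ok)) next
      r <- num[ok] / ref[ok]
      ws <- w[rows][ok]
      byProt <- split(seq_along(r), prot[rows][ok])
      for (g in names(byProt)) {
        i <- byProt[[g]]
        counts[g, s] <- length(i)
        if (length(i) >= config$minPSMs && sum(ws[i]) > 0)
          values[g, s] <- weightedMedian(r[i], ws[i])
      }
    }
  }
  .quantMatrix(values, counts, design, kind = "wm_normalized",
               config = unclass(config))
}
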