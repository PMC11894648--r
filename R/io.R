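# Numbers are written with "%.17g" so that every double survives a
# write -> read round trip bit-exactly; missing values are empty fields.
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

.writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
    else {
      v <- as.character(out[[j]])
      v[is.na(v)] <- ""
      out[[j]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

.psmNumericCols <- function(nms) {
  c(grep("^Reporter intensity( corrected)? [0-9]+$", nms, value = TRUE),
    intersect(c("Precursor intensity", "Ion injection time", "PIF",
                "Base peak ratio"), nms))
}

#' Read / write a PSM table in the MaxQuant column dialect
#'
#' The table is TSV with columns \code{Reporter intensity 1..n}
#' (contiguous 1-based channel indices; the channel count is inferred
#' from them), optionally \code{Reporter intensity corrected 1..n},
#' \code{Precursor intensity}, \code{Ion injection time}, \code{PIF},
#' \code{Base peak ratio}, mandatory \code{Proteins} (protein-group
#' assignment) and \code{Experiment}, and a plex identifier column
#' (default \code{Plex}; falls back to \code{Experiment} when absent).
#' Unparseable numeric cells become missing with a logged count.
#'
#' @param path file path.
#' @param plexColumn name of the plex identifier column.
#' @return a PSM data.frame.
#' @export
readPSMTable <- function(path, plexColumn = "Plex") {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    na.strings = "", fileEncoding = "UTF-8")
  miss <- setdiff(c("Reporter intensity 1", "Proteins", "Experiment"),
                  names(tab))
  if (length(miss))
    stop("PSM table misses mandatory column(s): ",
         paste(miss, collapse = ", "))
  nbad <- 0L
  for (col in .psmNumericCols(names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    nbad <- nbad + sum(is.na(v) & !is.na(tab[[col]]))
    tab[[col]] <- v
  }
  if (nbad > 0L)
    message("readPSMTable: ", nbad,
            " unparseable numeric cell(s) set to missing")
  n <- .psmChannelCount(tab)
  nc <- length(grep("^Reporter intensity [0-9]+$", names(tab)))
  if (nc != n)
    stop("non-contiguous 'Reporter intensity <k>' columns: found ", nc,
         " columns but contiguous run of ", n)
  ncor <- .psmChannelCount(tab, corrected = TRUE)
  if (ncor > 0L && ncor != n)
    stop("corrected reporter columns (", ncor,
         ") do not match the raw channel count (", n, ")")
  tab
}

#' @rdname readPSMTable
#' @param psm PSM data.frame.
#' @export
writePSMTable <- function(psm, path) {
  .writeTsv(psm, path)
  invisible(path)
}

# wide-format sample column name in the proteinGroups dialect
.quantWideNames <- function(qm) {
  channels <- S4Vectors::metadata(qm)$channels
  cd <- SummarizedExperiment::colData(qm)
  k <- match(cd$channel, channels)
  prefix <- if (quantKind(qm) == "summed_raw") "Reporter intensity "
            else "Reporter intensity corrected "
  paste0(prefix, k, " ", cd$plex)
}

#' Write / read a quantification matrix
#'
#' The wide format follows the MaxQuant proteinGroups dialect: one row
#' per protein group, one column per sample named
#' \code{Reporter intensity [corrected] <k> <plex>} with \code{<k>} the
#' 1-based channel index in label-set order.  Missing values are empty
#' fields.  \code{longPath} additionally writes a tidy long table with
#' one row per (protein group, sample) pair including the PSM support
#' count.
#'
#' @param qm a [QuantMatrix-class].
#' @param path output path of the wide TSV.
#' @param longPath optional output path of the tidy long TSV.
#' @return \code{path}, invisibly.
#' @export
writeQuantMatrix <- function(qm, path, longPath = NULL) {
  stopifnot(is(qm, "QuantMatrix"))
  V <- quantValues(qm)
  wide <- data.frame(`Protein group` = rownames(V), check.names = FALSE)
  wide[.quantWideNames(qm)] <- as.data.frame(V)
  .writeTsv(wide, path)
  if (!is.null(longPath)) {
    cd <- SummarizedExperiment::colData(qm)
    long <- data.frame(
      protein = rep(rownames(V), times = ncol(V)),
      sample = rep(colnames(V), each = nrow(V)),
      plex = rep(cd$plex, each = nrow(V)),
      channel = rep(cd$channel, each = nrow(V)),
      group = rep(cd$group, each = nrow(V)),
      value = as.vector(V),
      nPSM = as.vector(psmCounts(qm)))
    .writeTsv(long, longPath)
  }
  invisible(path)
}

#' @rdname writeQuantMatrix
#' @param design the [ExperimentalDesign-class] the matrix was computed
#'   against (provides sample/column mapping).
#' @param kind the quantification kind stored in the file
#'   (\code{"wm_normalized"}, \code{"summed_raw"} or
#'   \code{"summed_corrected"}).
#' @export
readQuantMatrix <- function(path, design, kind = "wm_normalized") {
  stopifnot(is(design, "ExperimentalDesign"))
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    na.strings = "", fileEncoding = "UTF-8")
  if (!"Protein group" %in% names(tab))
    stop("not a quantification matrix file (no 'Protein group' column)")
  si <- sampleInfo(design)
  k <- match(si$channel, channelNames(design@labelSet))
  prefix <- if (kind == "summed_raw") "Reporter intensity "
            else "Reporter intensity corrected "
  cols <- paste0(prefix, k, " ", si$plex)
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("quantification matrix misses column(s): ",
         paste(miss, collapse = ", "))
  V <- sapply(cols, function(cn) as.numeric(tab[[cn]]))
  V <- matrix(as.numeric(V), nrow = nrow(tab),
              dimnames = list(tab[["Protein group"]], rownames(si)))
  counts <- matrix(NA_integer_, nrow(V), ncol(V), dimnames = dimnames(V))
  .quantMatrix(V, counts, design, kind = kind, config = NULL)
}

#' Read / write a 2-D embedding
#'
#' TSV with columns \code{sample}, \code{dim1}, \code{dim2}; the entry
#' point for externally computed t-SNE/UMAP coordinates.
#'
#' @param path file path.
#' @param method stored method label for a read embedding.
#' @return [readEmbedding()] returns an [Embedding-class].
#' @export
readEmbedding <- function(path, method = "external") {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, fileEncoding = "UTF-8")
  if (!all(c("sample", "dim1", "dim2") %in% names(tab)))
    stop("embedding file needs columns sample, dim1, dim2")
  co <- as.matrix(tab[c("dim1", "dim2")])
  rownames(co) <- tab$sample
  embedding(co, method = method)
}

#' @rdname readEmbedding
#' @param emb an [Embedding-class].
#' @export
writeEmbedding <- function(emb, path) {
  co <- embeddingCoords(emb)
  .writeTsv(data.frame(sample = rownames(co), dim1 = co[, 1],
                       dim2 = co[, 2]), path)
  invisible(path)
}
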