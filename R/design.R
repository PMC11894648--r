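#' Construct an experimental design
#'
#' @param labelSet the [LabelSet-class] shared by all plexes.
#' @param table data.frame with columns \code{plex}, \code{channel},
#'   \code{role} (\code{sample}/\code{reference}/\code{carrier}/\code{empty}),
#'   \code{sample} (unique names, sample channels only) and \code{group}.
#' @return an [ExperimentalDesign-class].
#' @export
experimentalDesign <- function(labelSet, table) {
  labelSet <- .asLabelSet(labelSet)
  table <- as.data.frame(table)
  for (col in c("plex", "channel", "role", "sample", "group"))
    if (!is.null(table[[col]])) table[[col]] <- as.character(table[[col]])
  new("ExperimentalDesign", labelSet = labelSet, table = table)
}

#' @rdname ExperimentalDesign-class
#' @export
setMethod("designTable", "ExperimentalDesign", function(x) x@table)

#' @rdname ExperimentalDesign-class
#' @export
setMethod("sampleInfo", "ExperimentalDesign", function(x) {
  t <- x@table[x@table$role == "sample", , drop = FALSE]
  # fixed sample order: plex in order of first appearance, channel in
  # label-set order within a plex
  t <- t[order(match(t$plex, unique(x@table$plex)),
               match(t$channel, channelNames(x@labelSet))), , drop = FALSE]
  rownames(t) <- t$sample
  t
})

#' @rdname ExperimentalDesign-class
#' @export
setMethod("channelNames", "ExperimentalDesign",
          function(x) channelNames(x@labelSet))

#' @rdname ExperimentalDesign-class
#' @export
setMethod("nChannels", "ExperimentalDesign",
          function(x) nChannels(x@labelSet))

#' @export
setMethod("show", "ExperimentalDesign", function(object) {
  t <- object@table
  cat("ExperimentalDesign: ", length(unique(t$plex)), " plex(es) x ",
      nChannels(object@labelSet), " channels (",
      object@labelSet@name, ")\n", sep = "")
  cat("  samples: ", sum(t$role == "sample"),
      "; reference channels: ", sum(t$role == "reference"),
      "; carrier: ", sum(t$role == "carrier"),
      "; empty: ", sum(t$role == "empty"), "\n", sep = "")
})

#' @export
#' @rdname ExperimentalDesign-class
plexNames <- function(x) unique(designTable(x)$plex)

# channel indices (1-based, label-set order) of a role within one plex
.roleIndices <- function(design, plex, role) {
  t <- design@table
  ch <- t$channel[t$plex == plex & t$role %in% role]
  sort(match(ch, channelNames(design@labelSet)))
}

#' Read / write a design file
#'
#' Design files are TSV with columns \code{plex}, \code{channel},
#' \code{role}, \code{sample}, \code{group}; empty fields mean NA.
#'
#' @param path file path.
#' @param labelSet the [LabelSet-class] the design refers to.
#' @return [readDesign()] returns an [ExperimentalDesign-class];
#'   [writeDesign()] returns \code{path} invisibly.
#' @export
readDesign <- function(path, labelSet) {
  if (!file.exists(path)) stop("design file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    na.strings = "", fileEncoding = "UTF-8")
  need <- c("plex", "channel", "role", "sample", "group")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("design file misses column(s): ", paste(miss, collapse = ", "))
  experimentalDesign(labelSet, tab[need])
}

#' @rdname readDesign
#' @param design an [ExperimentalDesign-class].
#' @export
writeDesign <- function(design, path) {
  stopifnot(is(design, "ExperimentalDesign"))
  .writeTsv(designTable(design), path)
  invisible(path)
}
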