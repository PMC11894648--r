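#' @import methods
#' @importFrom stats median prcomp pchisq rnorm runif rpois lm anova setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' LabelSet: the channel structure of one isobaric n-plex
#'
#' An ordered set of reporter channels for one isobaric labeling reagent
#' set (e.g. TMT 10-plex).  The channel order is fixed and defines the
#' row/column order of every mixing matrix and reporter-intensity vector
#' associated with the label set.
#'
#' @slot name single string naming the reagent set (e.g. \code{"TMT10"}).
#' @slot channels character vector of unique channel names in
#'   monoisotopic-mass order (N before C within a nominal mass).
#'
#' @seealso [labelSet()] for construction and the built-in presets.
#' @export
setClass("LabelSet",
  slots = c(name = "character", channels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name))
      msg <- c(msg, "'name' must be a single non-NA string")
    ch <- object@channels
    if (length(ch) < 1L || anyNA(ch) || any(!nzchar(ch)))
      msg <- c(msg, "'channels' must be a non-empty vector of non-NA names")
    if (anyDuplicated(ch))
      msg <- c(msg, "channel names must be unique")
    if (length(msg)) msg else TRUE
  })

#' CorrectionFactors: off-diagonal impurity leakage fractions
#'
#' Isotopic impurities of each label cause a fraction of its reporter
#' signal to appear in other channels.  Each entry states the fraction
#' (dimensionless, in [0,1)) of a source channel's true signal observed
#' in a destination channel.  The diagonal is implied as the remainder.
#'
#' @slot labelSet the [LabelSet-class] the factors refer to.
#' @slot entries data.frame with columns \code{source}, \code{destination}
#'   (channel names) and \code{fraction}.
#'
#' @seealso [correctionFactors()], [readCorrectionTemplate()],
#'   [buildMixingMatrix()]
#' @export
setClass("CorrectionFactors",
  slots = c(labelSet = "LabelSet", entries = "data.frame"),
  validity = function(object) {
    msg <- character()
    e <- object@entries
    need <- c("source", "destination", "fraction")
    if (!all(need %in% names(e)))
      return("'entries' must have columns source, destination, fraction")
    ch <- channelNames(object@labelSet)
    bad <- setdiff(unique(c(e$source, e$destination)), ch)
    if (length(bad))
      msg <- c(msg, paste0("unknown channel name(s): ",
                           paste(bad, collapse = ", ")))
    if (any(e$source == e$destination))
      msg <- c(msg, "destination must differ from source")
    if (anyDuplicated(e[c("source", "destination")]))
      msg <- c(msg, "duplicate (source, destination) pair")
    if (any(!is.finite(e$fraction)) || any(e$fraction < 0) ||
        any(e$fraction >= 1))
      msg <- c(msg, "fractions must be finite and in [0, 1)")
    if (nrow(e)) {
      tot <- tapply(e$fraction, e$source, sum)
      if (any(tot >= 1))
        msg <- c(msg, paste0("off-diagonal fractions sum to >= 1 for source ",
                             paste(names(tot)[tot >= 1], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  })

#' MixingMatrix: row-normalized impurity mixing weights
#'
#' The n x n matrix A relating true to observed reporter intensities.
#' Row i holds the distribution of channel i's true signal over observed
#' channels, so rows are mixing weights normalized to 1 and the observed
#' vector is \eqn{y = A^T x}.
#'
#' @slot A numeric n x n matrix, entries >= 0, each row summing to 1.
#' @slot labelSet the associated [LabelSet-class]; channel order fixes
#'   the row/column order of \code{A}.
#'
#' @seealso [buildMixingMatrix()], [correctImpurities()]
#' @export
setClass("MixingMatrix",
  slots = c(A = "matrix", labelSet = "LabelSet"),
  validity = function(object) {
    msg <- character()
    A <- object@A
    n <- nChannels(object@labelSet)
    if (!is.numeric(A) || nrow(A) != n || ncol(A) != n)
      return("'A' must be a numeric n x n matrix matching the label set")
    if (any(!is.finite(A)) || any(A < 0))
      msg <- c(msg, "entries of 'A' must be finite and >= 0")
    if (any(abs(rowSums(A) - 1) > 1e-12))
      msg <- c(msg, "rows of 'A' must sum to 1 within 1e-12")
    if (length(msg)) msg else TRUE
  })

#' ExperimentalDesign: channel roles and sample annotations per plex
#'
#' Maps, for every plex, each channel of the label set to a role
#' (\code{sample}, \code{reference}, \code{carrier} or \code{empty}) and
#' annotates sample channels with unique sample names and a group label
#' (tissue, condition, ...).  Carrier and empty channels never contribute
#' to reference intensities in any normalization mode.
#'
#' @slot labelSet the [LabelSet-class] shared by all plexes.
#' @slot table data.frame with columns \code{plex}, \code{channel},
#'   \code{role}, \code{sample}, \code{group}; one row per plex/channel.
#'
#' @seealso [experimentalDesign()], [readDesign()], [wmNormalize()]
#' @export
setClass("ExperimentalDesign",
  slots = c(labelSet = "LabelSet", table = "data.frame"),
  validity = function(object) {
    msg <- character()
    t <- object@table
    need <- c("plex", "channel", "role", "sample", "group")
    if (!all(need %in% names(t)))
      return("'table' must have columns plex, channel, role, sample, group")
    roles <- c("sample", "reference", "carrier", "empty")
    if (!all(t$role %in% roles))
      msg <- c(msg, paste0("roles must be one of ",
                           paste(roles, collapse = "/")))
    ch <- channelNames(object@labelSet)
    for (p in unique(t$plex)) {
      tp <- t[t$plex == p, ]
      if (nrow(tp) != length(ch) || !setequal(tp$channel, ch))
        msg <- c(msg, paste0("plex '", p, "' must list every channel of ",
                             "the label set exactly once"))
      if (!any(tp$role == "sample"))
        msg <- c(msg, paste0("plex '", p, "' has no sample channel"))
    }
    sn <- t$sample[t$role == "sample"]
    if (anyNA(sn) || any(!nzchar(sn)))
      msg <- c(msg, "every sample channel needs a sample name")
    if (anyDuplicated(sn))
      msg <- c(msg, "sample names must be unique across the design")
    if (length(msg)) msg else TRUE
  })

#' QuantMatrix: protein groups x samples quantification container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding per-protein-group,
#' per-sample quantitative values with their PSM support counts.  The
#' \code{"quant"} assay holds either summed reporter intensities
#' (\code{kind} \code{"summed_raw"} / \code{"summed_corrected"}) or
#' weighted-median normalized sample/reference ratios
#' (\code{kind} \code{"wm_normalized"}).  Column metadata carries the
#' sample, plex, channel and group annotations from the design; the
#' provenance (kind and normalization configuration) lives in
#' \code{metadata()}.
#'
#' @seealso [aggregateSum()], [wmNormalize()], [quantValues()],
#'   [writeQuantMatrix()]
#' @export
setClass("QuantMatrix", contains = "SummarizedExperiment")

#' Embedding: 2-D sample coordinates
#'
#' A two-dimensional embedding of the samples of a [QuantMatrix-class],
#' either computed internally by PCA or supplied externally (t-SNE/UMAP
#' coordinates from other tools).
#'
#' @slot coordinates numeric samples x 2 matrix with sample row names.
#' @slot method \code{"pca"} or \code{"external"}.
#'
#' @seealso [pcaEmbed()], [readEmbedding()], [wilksLambda()]
#' @export
setClass("Embedding",
  slots = c(coordinates = "matrix", method = "character"),
  validity = function(object) {
    msg <- character()
    co <- object@coordinates
    if (!is.numeric(co) || ncol(co) != 2L)
      return("'coordinates' must be a numeric samples x 2 matrix")
    if (any(!is.finite(co)))
      msg <- c(msg, "coordinates must be finite")
    if (is.null(rownames(co)) || anyDuplicated(rownames(co)))
      msg <- c(msg, "coordinates need unique sample row names")
    if (!identical(length(object@method), 1L) ||
        !object@method %in% c("pca", "external"))
      msg <- c(msg, "'method' must be \"pca\" or \"external\"")
    if (length(msg)) msg else TRUE
  })

#' GroupingResult: MANOVA separation of a sample grouping
#'
#' Wilks' lambda and its chi-square p-value for one grouping of the
#' samples of a 2-D embedding.  Lambda near 1 means no group separation,
#' near 0 strong separation.
#'
#' @slot wilksLambda Wilks' lambda, in (0, 1].
#' @slot pValue p-value from Bartlett's chi-square approximation.
#' @slot grouping name of the grouping variable tested.
#' @slot nGroups,nSamples group and sample counts.
#' @slot ridged TRUE when a numerical ridge was added to a singular
#'   within-group scatter matrix.
#'
#' @seealso [wilksLambda()]
#' @export
setClass("GroupingResult",
  slots = c(wilksLambda = "numeric", pValue = "numeric",
            grouping = "character", nGroups = "integer",
            nSamples = "integer", ridged = "logical"),
  validity = function(object) {
    msg <- character()
    if (!(object@wilksLambda > 0 && object@wilksLambda <= 1 + 1e-12))
      msg <- c(msg, "wilksLambda must lie in (0, 1]")
    if (object@pValue < 0 || object@pValue > 1)
      msg <- c(msg, "pValue must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })
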