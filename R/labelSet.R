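.asLabelSet <- function(x) if (is(x, "LabelSet")) x else labelSet(x)

# Preset channel orderings: monoisotopic-mass order, N before C within a
# nominal reporter mass.
.labelPresets <- list(
  TMT10 = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
            "130N", "130C", "131"),
  TMT11 = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
            "130N", "130C", "131", "131C"),
  TMTpro16 = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
               "130N", "130C", "131N", "131C", "132N", "132C", "133N",
               "133C", "134N")
)

#' Construct a label set
#'
#' Builds a [LabelSet-class] either from a preset name (\code{"TMT10"},
#' \code{"TMT11"}, \code{"TMTpro16"}) or from an explicit ordered vector
#' of channel names.
#'
#' @param x a single preset name, or a character vector of >= 2 channel
#'   names in the desired fixed order.
#' @param name optional name for an explicitly defined set.
#' @return a [LabelSet-class].
#' @examples
#' labelSet("TMT10")
#' labelSet(c("A", "B"), name = "duplex")
#' @export
labelSet <- function(x, name = NULL) {
  if (is(x, "LabelSet")) return(x)
  if (!is.character(x) || length(x) < 1L)
    stop("'x' must be a preset name or a character vector of channels")
  if (length(x) == 1L) {
    if (!x %in% names(.labelPresets))
      stop("unknown label set preset '", x, "'; available: ",
           paste(names(.labelPresets), collapse = ", "))
    return(new("LabelSet", name = x, channels = .labelPresets[[x]]))
  }
  new("LabelSet", name = if (is.null(name)) "custom" else name,
      channels = as.character(x))
}

#' @rdname LabelSet-class
#' @export
setMethod("channelNames", "LabelSet", function(x) x@channels)

#' @rdname LabelSet-class
#' @export
setMethod("nChannels", "LabelSet", function(x) length(x@channels))

#' @export
setMethod("show", "LabelSet", function(object) {
  cat("LabelSet \"", object@name, "\" with ", nChannels(object),
      " channels:\n  ", paste(channelNames(object), collapse = " "),
      "\n", sep = "")
})

#' Construct impurity correction factors
#'
#' @param labelSet a [LabelSet-class] (or preset name).
#' @param source,destination,fraction parallel vectors: fraction (in
#'   [0,1)) of each source channel's true signal observed in the
#'   destination channel.  All empty gives the identity correction.
#' @return a [CorrectionFactors-class].
#' @examples
#' correctionFactors(labelSet(c("A", "B")), "A", "B", 0.1)
#' @export
correctionFactors <- function(labelSet, source = character(),
                              destination = character(),
                              fraction = numeric()) {
  labelSet <- .asLabelSet(labelSet)
  new("CorrectionFactors", labelSet = labelSet,
      entries = data.frame(source = as.character(source),
                           destination = as.character(destination),
                           fraction = as.numeric(fraction)))
}

#' @export
setMethod("show", "CorrectionFactors", function(object) {
  cat("CorrectionFactors for ", object@labelSet@name, ": ",
      nrow(object@entries), " off-diagonal entries\n", sep = "")
})

#' Read an impurity correction-factor template file
#'
#' Templates are UTF-8 TSV files with the header
#' \code{source<TAB>destination<TAB>percent}; lines starting with
#' \code{#} are ignored.  Destinations are named channels (not mass
#' offsets), which keeps C-type vs N-type leakage unambiguous for
#' reagents such as TMTpro where one source leaks into both a C and an N
#' channel of the next nominal mass.  Percentages are converted to
#' fractions; an empty template yields the identity correction.
#'
#' @param path template file path.
#' @param labelSet the [LabelSet-class] the template refers to.
#' @return a [CorrectionFactors-class].
#' @examples
#' tf <- system.file("extdata", "tmtpro16_impurities_synthetic.tsv",
#'                   package = "plexquant")
#' readCorrectionTemplate(tf, labelSet("TMTpro16"))
#' @export
readCorrectionTemplate <- function(path, labelSet) {
  labelSet <- .asLabelSet(labelSet)
  if (!file.exists(path)) stop("template file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = TRUE,
                    blank.lines.skip = TRUE, fileEncoding = "UTF-8")
  if (nrow(tab) == 0L)
    return(correctionFactors(labelSet))
  if (!all(c("source", "destination", "percent") %in% names(tab)))
    stop("template must have header 'source\\tdestination\\tpercent'")
  pct <- suppressWarnings(as.numeric(tab$percent))
  bad <- which(!is.finite(pct) | pct < 0 | pct > 100)
  if (length(bad))
    stop("percent outside [0, 100] (or not numeric) in template row(s) ",
         paste(bad, collapse = ", "))
  ch <- channelNames(labelSet)
  unknown <- which(!(tab$source %in% ch) | !(tab$destination %in% ch))
  if (length(unknown))
    stop("unknown channel name in template row(s) ",
         paste(unknown, collapse = ", "), ": ",
         paste(unique(c(tab$source[unknown], tab$destination[unknown])),
               collapse = ", "))
  correctionFactors(labelSet, tab$source, tab$destination, pct / 100)
}

#' Build the impurity mixing matrix
#'
#' Places each correction-factor entry at \code{A[source, destination]}
#' and sets the diagonal to the remainder, so every row sums to exactly
#' one.  An empty set of factors yields the identity matrix.
#'
#' @param labelSet a [LabelSet-class] (or preset name).
#' @param cf a [CorrectionFactors-class] for that label set.
#' @return a [MixingMatrix-class].
#' @examples
#' ls2 <- labelSet(c("A", "B"))
#' buildMixingMatrix(ls2, correctionFactors(ls2, "A", "B", 0.1))
#' @export
buildMixingMatrix <- function(labelSet, cf) {
  labelSet <- .asLabelSet(labelSet)
  stopifnot(is(cf, "CorrectionFactors"))
  if (!identical(channelNames(cf@labelSet), channelNames(labelSet)))
    stop("correction factors were defined for a different label set")
  ch <- channelNames(labelSet)
  n <- length(ch)
  A <- matrix(0, n, n, dimnames = list(ch, ch))
  e <- cf@entries
  if (nrow(e))
    A[cbind(match(e$source, ch), match(e$destination, ch))] <- e$fraction
  diag(A) <- 0
  d <- 1 - rowSums(A)
  if (any(d <= 0))
    stop("over-specified leakage: off-diagonal fractions leave a ",
         "non-positive diagonal for channel(s) ",
         paste(ch[d <= 0], collapse = ", "))
  diag(A) <- d
  new("MixingMatrix", A = A, labelSet = labelSet)
}

#' @rdname MixingMatrix-class
#' @export
setMethod("mixingMatrix", "MixingMatrix", function(x) x@A)

#' @export
setMethod("show", "MixingMatrix", function(object) {
  cat("MixingMatrix (", nChannels(object@labelSet), " x ",
      nChannels(object@labelSet), ") for ", object@labelSet@name, "\n",
      sep = "")
  od <- object@A; diag(od) <- 0
  cat("  total off-diagonal leakage: ",
      format(sum(od), digits = 4), "\n", sep = "")
})

# Solve the reduced system t(A)[keep, keep] x = y[keep] for one block of
# rows sharing a zero pattern.  Y is nPSM x n.  Returns corrected block.
.correctBlock <- function(Y, At, keep) {
  X <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  if (!any(keep)) return(X)
  Ar <- At[keep, keep, drop = FALSE]
  sol <- tryCatch(solve(Ar, t(Y[, keep, drop = FALSE])),
                  error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular reduced impurity system; raw intensities passed ",
            "through unchanged for ", nrow(Y), " spectrum/spectra",
            call. = FALSE)
    X[, keep] <- Y[, keep]
  } else {
    X[, keep] <- pmax(t(sol), 0)
  }
  X
}

#' @rdname correctImpurities
#' @export
setMethod("correctImpurities", signature(y = "numeric", M = "MixingMatrix"),
  function(y, M) {
    n <- nChannels(M@labelSet)
    if (length(y) != n) stop("'y' must have length ", n)
    if (anyNA(y) || any(y < 0)) stop("'y' must be non-negative")
    drop(correctImpurities(matrix(y, 1L, n,
                                  dimnames = list(NULL, channelNames(M@labelSet))),
                           M))
  })

#' @rdname correctImpurities
#' @export
setMethod("correctImpurities", signature(y = "matrix", M = "MixingMatrix"),
  function(y, M) {
    n <- nChannels(M@labelSet)
    if (ncol(y) != n) stop("'y' must have ", n, " columns")
    if (anyNA(y) || any(y < 0)) stop("'y' must be non-negative")
    At <- t(M@A)
    # rows sharing a zero pattern share one LU factorization
    pat <- apply(y > 0, 1L, function(k) paste(as.integer(k), collapse = ""))
    X <- y
    for (p in unique(pat)) {
      idx <- which(pat == p)
      keep <- strsplit(p, "")[[1]] == "1"
      X[idx, ] <- .correctBlock(y[idx, , drop = FALSE], At, keep)
    }
    X
  })
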