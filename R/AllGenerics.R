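#' @rdname LabelSet-class
#' @param x a \code{LabelSet} (or object holding one).
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname LabelSet-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname MixingMatrix-class
#' @param x a \code{MixingMatrix}.
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))

#' Correct observed reporter intensities for isotopic impurities
#'
#' Inverts the impurity mixing \eqn{y = A^T x} for one reporter vector or
#' for every row of a PSM reporter matrix.  Channels with an observed
#' intensity of exactly zero are removed from the system (rows and
#' columns of A alike) before solving; the reduced square system is
#' solved by dense LU factorization; negative solution elements are
#' clamped to zero; removed channels report a corrected intensity of 0.
#' A singular reduced system leaves that spectrum's raw values unchanged
#' and emits a warning, so no spectrum is silently dropped.
#'
#' @param y non-negative observed reporter intensities: a length-n numeric
#'   vector, or a numeric matrix with n columns (one row per PSM).
#' @param M a [MixingMatrix-class].
#' @return corrected intensities, same shape as \code{y}.
#' @examples
#' ls2 <- labelSet(c("A", "B"))
#' cf <- correctionFactors(ls2, source = "A", destination = "B",
#'                         fraction = 0.1)
#' M <- buildMixingMatrix(ls2, cf)
#' correctImpurities(c(90, 60), M)  # recovers c(100, 50)
#' @export
setGeneric("correctImpurities", function(y, M) {
  standardGeneric("correctImpurities")
})

#' @rdname QuantMatrix-class
#' @param x a \code{QuantMatrix}.
#' @export
setGeneric("quantValues", function(x) standardGeneric("quantValues"))

#' @rdname QuantMatrix-class
#' @export
setGeneric("psmCounts", function(x) standardGeneric("psmCounts"))

#' @rdname QuantMatrix-class
#' @export
setGeneric("quantKind", function(x) standardGeneric("quantKind"))

#' @rdname Embedding-class
#' @param x an \code{Embedding}.
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @rdname ExperimentalDesign-class
#' @param x an \code{ExperimentalDesign}.
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname ExperimentalDesign-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
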