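#' Weighted median with an exact-half midpoint tie rule
#'
#' Values are sorted ascending (stable); the weighted median is the first
#' value whose cumulative weight reaches half the total weight.  When the
#' cumulative weight at a value equals exactly half the total, the result
#' is the arithmetic mean of that value and the next distinct value, so
#' that equal weights reduce to the ordinary even-count median
#' convention.  Any returned value minimizes \eqn{\sum_i w_i |v_i - m|}.
#'
#' @param values numeric vector.
#' @param weights non-negative numeric weights, same length, at least one
#'   positive.
#' @return the weighted median (a single number).
#' @examples
#' weightedMedian(c(1, 2, 3), c(1, 1, 1))   # 2
#' weightedMedian(c(1, 2, 10), c(1, 1, 3))  # 10
#' weightedMedian(c(1, 3), c(1, 1))         # 2 (exact-half tie)
#' @export
weightedMedian <- function(values, weights) {
  if (length(values) == 0L) stop("empty input")
  if (length(weights) != length(values))
    stop("'values' and 'weights' must have the same length")
  if (anyNA(values) || anyNA(weights) || any(weights < 0))
    stop("values must be non-NA and weights non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("all weights are zero")
  o <- order(values)            # stable in R
  v <- values[o]
  cw <- cumsum(weights[o])
  half <- tot / 2
  i <- which(cw >= half)[1L]
  if (cw[i] == half) {
    nxt <- which(v > v[i])
    if (length(nxt)) return((v[i] + v[nxt[1L]]) / 2)
  }
  v[i]
}

#' PSM quantification weight
#'
#' The weight of a PSM for weighted-median normalization: the product of
#' the precursor ion intensity at the MS/MS retention time and the ion
#' injection (fill) time of the MS/MS spectrum -- proportional to the
#' number of ions fragmented -- raised to a user-set exponent (the
#' isobaric weight exponent).  Exponent 0 gives unweighted medians.  A
#' missing precursor intensity or fill time contributes a factor of 1 so
#' the PSM is down-weighted rather than discarded.
#'
#' @param precursorIntensity,fillTime numeric vectors (NA allowed).
#' @param exponent single non-negative number.
#' @return numeric vector of weights.
#' @examples
#' psmWeight(1e6, 10, 1)    # 1e7
#' psmWeight(4, 9, 0.5)     # 6
#' psmWeight(NA, NA, 1)     # 1
#' @export
psmWeight <- function(precursorIntensity, fillTime, exponent = 1) {
  stopifnot(length(exponent) == 1L, is.finite(exponent), exponent >= 0)
  p <- ifelse(is.na(precursorIntensity), 1, precursorIntensity)
  f <- ifelse(is.na(fillTime), 1, fillTime)
  (p * f)^exponent
}
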