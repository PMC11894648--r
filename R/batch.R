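#' @rdname Embedding-class
#' @export
setMethod("embeddingCoords", "Embedding", function(x) x@coordinates)

#' @export
setMethod("show", "Embedding", function(object) {
  cat("Embedding (", object@method, "): ", nrow(object@coordinates),
      " samples x 2\n", sep = "")
})

#' Construct an Embedding from a coordinate matrix
#'
#' @param coordinates samples x 2 numeric matrix with sample row names.
#' @param method \code{"pca"} or \code{"external"} (t-SNE/UMAP
#'   coordinates computed by other tools).
#' @return an [Embedding-class].
#' @export
embedding <- function(coordinates, method = "external") {
  co <- as.matrix(coordinates)
  colnames(co) <- c("dim1", "dim2")
  new("Embedding", coordinates = co, method = method)
}

#' PCA embedding of a quantification matrix
#'
#' Projects the samples onto the first two principal components of the
#' (optionally log-transformed) samples x proteins matrix, after
#' centering each protein across samples.  Only proteins quantified in
#' every sample are used (\code{naPolicy = "complete"}); imputation is
#' deliberately not offered.  The component sign is fixed by making the
#' largest-magnitude loading of each component positive, so the
#' embedding is fully deterministic.
#'
#' @param qm a [QuantMatrix-class] (or a proteins x samples numeric
#'   matrix).
#' @param log2Transform take log2 of the values first (rows with any
#'   non-positive value are then dropped as incomplete).
#' @param naPolicy only \code{"complete"} (complete rows) is supported.
#' @return an [Embedding-class] with \code{method = "pca"}.
#' @export
pcaEmbed <- function(qm, log2Transform = TRUE, naPolicy = "complete") {
  naPolicy <- match.arg(naPolicy, "complete")
  X <- if (is(qm, "QuantMatrix")) quantValues(qm) else as.matrix(qm)
  if (ncol(X) < 3L) stop("need at least 3 samples")
  if (log2Transform) {
    X[!is.na(X) & X <= 0] <- NA
    X <- log2(X)
  }
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L)
    stop("fewer than 3 complete protein rows; cannot embed")
  pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  if (k < 2L) stop("degenerate data: fewer than 2 principal components")
  co <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {                    # deterministic sign convention
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) co[, j] <- -co[, j]
  }
  rownames(co) <- colnames(X)
  embedding(co, method = "pca")
}

.groupLabels <- function(emb, groups) {
  g <- factor(groups)
  if (length(g) != nrow(embeddingCoords(emb)))
    stop("'groups' must have one label per embedded sample")
  if (anyNA(g)) stop("group labels must not be NA")
  g
}

#' Wilks' lambda MANOVA of a sample grouping on a 2-D embedding
#'
#' Computes \eqn{\Lambda = \det(W) / \det(W + B)} where W is the pooled
#' within-group scatter and B the between-group scatter of the 2-D
#' coordinates, and a p-value from Bartlett's chi-square approximation
#' \eqn{-(N - 1 - (d + g)/2) \ln\Lambda \sim \chi^2_{d(g-1)}} with d = 2
#' dimensions, g groups and N samples.  Lambda near 1 means the grouping
#' explains no coordinate variance (no batch/biology separation), near 0
#' strong separation.  A singular W is stabilized by a ridge of
#' \code{1e-12 * trace(W)} and flagged in the result.
#'
#' @param emb an [Embedding-class].
#' @param groups one label per sample (embedding row order).
#' @param grouping name of the grouping variable (for reporting).
#' @return a [GroupingResult-class].
#' @export
wilksLambda <- function(emb, groups, grouping = "group") {
  g <- .groupLabels(emb, groups)
  X <- embeddingCoords(emb)
  N <- nrow(X); d <- ncol(X); ng <- nlevels(g)
  if (ng < 2L) stop("need at least 2 groups")
  if (N <= ng + 2L) stop("need more samples than groups + 2")
  grand <- colMeans(X)
  W <- matrix(0, d, d); B <- matrix(0, d, d)
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mi)
    W <- W + crossprod(Xc)
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
  }
  ridged <- FALSE
  if (!(det(W) > 0)) {
    W <- W + diag(1e-12 * sum(diag(W)) + .Machine$double.xmin, d)
    ridged <- TRUE
  }
  lambda <- det(W) / det(W + B)
  lambda <- min(max(lambda, .Machine$double.xmin), 1)
  stat <- -(N - 1 - (d + ng) / 2) * log(lambda)
  p <- pchisq(stat, df = d * (ng - 1), lower.tail = FALSE)
  new("GroupingResult", wilksLambda = lambda, pValue = p,
      grouping = grouping, nGroups = ng, nSamples = N, ridged = ridged)
}

#' @export
setMethod("show", "GroupingResult", function(object) {
  cat("MANOVA of grouping '", object@grouping, "' (", object@nGroups,
      " groups, ", object@nSamples, " samples)\n", sep = "")
  cat("  Wilks' lambda = ", format(object@wilksLambda, digits = 5),
      ", p = ", format(object@pValue, digits = 5),
      if (object@ridged) "  [ridged W]" else "", "\n", sep = "")
})

#' One-way ANOVA separation score on the first principal component
#'
#' Scores how well a sample grouping is separated along PC1: the
#' \eqn{-\log_{10}} of the one-way fixed-effects ANOVA p-value of the
#' grouping on the PC1 coordinates.  High scores mean the grouping
#' dominates the main axis of variation; used to contrast biological
#' grouping against plex (batch) grouping before and after
#' normalization.  Underflowing p-values are capped at a score of 320.
#'
#' @param emb an [Embedding-class] (PC1 = first column).
#' @param groups one label per sample; every group needs >= 2 samples.
#' @return the score, a single number >= 0.
#' @export
pc1AnovaScore <- function(emb, groups) {
  g <- .groupLabels(emb, groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 samples")
  pc1 <- embeddingCoords(emb)[, 1]
  p <- anova(lm(pc1 ~ g))[["Pr(>F)"]][1]
  if (!is.finite(p) || p <= 0) return(320)
  min(-log10(p), 320)
}

#' Species ratio recovery as a function of the PIF threshold
#'
#' Sweeps a set of PIF thresholds: at each threshold the PSM table is
#' filtered ([pifFilter()]), weighted-median normalized
#' ([wmNormalize()]), and the difference of the median log2 ratio
#' between two condition groups is computed between two species protein
#' populations (foreground minus background).  With a constant
#' background proteome the background median is ~0, so the curve shows
#' how ratio compression from co-isolation relaxes as the threshold
#' tightens.
#'
#' @param psm PSM data.frame with a \code{PIF} column.
#' @param design an [ExperimentalDesign-class].
#' @param speciesMap named character vector protein group -> species.
#' @param conditionA,conditionB group labels of the numerator and
#'   denominator conditions.
#' @param foreground,background species names of the varied and the
#'   constant proteome.
#' @param thresholds PIF thresholds to sweep.
#' @param config a [wmConfig()] (its \code{pifThreshold} is overridden
#'   by the sweep).
#' @param plexColumn name of the plex identifier column.
#' @return data.frame with columns \code{threshold},
#'   \code{medianLog2Diff}, \code{nForeground}, \code{nBackground}.
#' @export
pifSweep <- function(psm, design, speciesMap, conditionA, conditionB,
                     foreground, background,
                     thresholds = c(0, 0.25, 0.5, 0.75, 0.9, 0.99),
                     config = wmConfig(), plexColumn = "Plex") {
  si <- sampleInfo(design)
  sa <- rownames(si)[si$group == conditionA]
  sb <- rownames(si)[si$group == conditionB]
  if (!length(sa) || !length(sb))
    stop("conditions not found in the design's group column")
  out <- lapply(thresholds, function(th) {
    cfg <- config; cfg$pifThreshold <- th
    qm <- wmNormalize(psm, design, cfg, plexColumn = plexColumn)
    V <- quantValues(qm)
    la <- rowMeans(V[, sa, drop = FALSE], na.rm = TRUE)
    lb <- rowMeans(V[, sb, drop = FALSE], na.rm = TRUE)
    l2 <- log2(la / lb)
    sp <- speciesMap[rownames(V)]
    fg <- l2[!is.na(l2) & is.finite(l2) & sp == foreground]
    bg <- l2[!is.na(l2) & is.finite(l2) & sp == background]
    data.frame(threshold = th,
               medianLog2Diff = median(fg) - median(bg),
               nForeground = length(fg), nBackground = length(bg))
  })
  do.call(rbind, out)
}
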