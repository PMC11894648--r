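# Independent oracles used across the suite.  These deliberately share
# no code with the package implementation.

# Brute-force reduced impurity solve: observed_i = sum_j A[j, i] x_j,
# built entry-by-entry and solved with qr.solve (QR, not LU).
bruteCorrect <- function(y, A) {
  n <- length(y)
  x <- numeric(n)
  keep <- which(y != 0)
  if (!length(keep)) return(x)
  B <- matrix(0, length(keep), length(keep))
  for (i in seq_along(keep))
    for (j in seq_along(keep))
      B[i, j] <- A[keep[j], keep[i]]
  sol <- qr.solve(B, y[keep])
  sol[sol < 0] <- 0
  x[keep] <- sol
  x
}

# random row-normalized diagonally dominant mixing matrix
randomMixing <- function(n, maxLeak = 0.3) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    nk <- min(n - 1L, sample(0:3, 1))
    k <- cand[sample.int(length(cand), nk)]
    if (length(k)) A[i, k] <- runif(length(k), 0, maxLeak / max(1, length(k)))
    A[i, i] <- 1 - sum(A[i, ])
  }
  A
}

mixingFromMatrix <- function(A) {
  ls <- labelSet(paste0("ch", seq_len(nrow(A))))
  dimnames(A) <- list(channelNames(ls), channelNames(ls))
  new("MixingMatrix", A = A, labelSet = ls)
}

# weighted-median objective; any weighted median must attain the grid
# minimum over the input values
wmObjective <- function(m, v, w) sum(w * abs(v - m))

# Wilks' lambda via stats::manova (independent of the package's scatter
# computation)
manovaWilks <- function(coords, groups) {
  g <- factor(groups)
  fit <- stats::manova(coords ~ g)
  summary(fit, test = "Wilks")$stats[1, "Wilks"]
}

# minimal two-channel design + PSM table builders for unit tests
tinyDesign <- function(roles = c("sample", "sample"),
                       channels = c("A", "B"),
                       groups = NULL, plex = "plex1") {
  ls <- labelSet(channels)
  samp <- ifelse(roles == "sample",
                 paste0("s", seq_along(roles), "_", plex), NA)
  if (is.null(groups)) groups <- ifelse(roles == "sample", "g1", NA)
  experimentalDesign(ls, data.frame(
    plex = plex, channel = channels, role = roles, sample = samp,
    group = groups))
}

tinyPSM <- function(Y, proteins, plex = "plex1", precursor = NULL,
                    fill = NULL, pif = NULL) {
  Y <- as.matrix(Y)
  tab <- data.frame(id = paste0("p", seq_len(nrow(Y))),
                    check.names = FALSE)
  tab[paste0("Reporter intensity ", seq_len(ncol(Y)))] <- as.data.frame(Y)
  tab[["Precursor intensity"]] <-
    if (is.null(precursor)) rep(1, nrow(Y)) else precursor
  tab[["Ion injection time"]] <- if (is.null(fill)) rep(1, nrow(Y)) else fill
  tab[["PIF"]] <- if (is.null(pif)) rep(1, nrow(Y)) else pif
  tab[["Base peak ratio"]] <- NA_real_
  tab[["Proteins"]] <- proteins
  tab[["Experiment"]] <- plex
  tab[["Plex"]] <- plex
  tab
}
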