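test_that("PCA embedding is deterministic and matches an
           eigendecomposition oracle", {
  set.seed(3)
  X <- matrix(rexp(50 * 10), 50, 10,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:10)))
  emb <- pcaEmbed(X, log2Transform = FALSE)
  co <- embeddingCoords(emb)
  expect_identical(rownames(co), colnames(X))
  # PC variances equal the top eigenvalues of the sample covariance
  ev <- eigen(stats::cov(t(X)), symmetric = TRUE)$values
  expect_equal(apply(co, 2, stats::var), ev[1:2], tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention makes the embedding reproducible
  expect_identical(co, embeddingCoords(pcaEmbed(X, log2Transform = FALSE)))

  # rank-1 data: PC1 orders samples by the driving protein
  drive <- seq(1, 10)
  X1 <- rbind(drive * 100, matrix(1, 3, 10))
  colnames(X1) <- paste0("s", 1:10)
  co1 <- embeddingCoords(pcaEmbed(X1, log2Transform = FALSE))
  expect_identical(order(co1[, 1]), seq_len(10))

  # duplicated sample -> identical coordinates
  Xd <- cbind(X, dup = X[, 1])
  cod <- embeddingCoords(pcaEmbed(Xd, log2Transform = FALSE))
  expect_equal(cod["dup", ], cod["s1", ])

  expect_error(pcaEmbed(X[1:2, ], log2Transform = FALSE),
               "fewer than 3 complete")
})

test_that("Wilks' lambda matches the MANOVA oracle and honors its
           analytic limits", {
  set.seed(8)
  # oracle agreement on random instances
  for (rep in 1:100) {
    ng <- sample(2:5, 1)
    n <- sample((ng + 4):30, 1)
    g <- sample(rep(letters[1:ng], length.out = n))
    co <- matrix(rnorm(2 * n), n, 2,
                 dimnames = list(paste0("s", 1:n), NULL))
    res <- wilksLambda(embedding(co), g)
    expect_equal(res@wilksLambda, manovaWilks(co, g), tolerance = 1e-10)
    expect_gt(res@wilksLambda, 0)
    expect_lte(res@wilksLambda, 1)
  }

  # forcing all group means equal kills B: lambda -> 1, p large
  n <- 24
  g <- rep(c("a", "b", "c"), each = 8)
  co <- matrix(rnorm(2 * n), n, 2, dimnames = list(paste0("s", 1:n), NULL))
  for (lev in unique(g))
    co[g == lev, ] <- sweep(co[g == lev, ], 2, colMeans(co[g == lev, ]))
  res <- wilksLambda(embedding(co), g)
  expect_equal(res@wilksLambda, 1, tolerance = 1e-10)
  expect_gt(res@pValue, 0.99)

  # two tight well-separated clusters: lambda ~ 0, p tiny
  co2 <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
               matrix(rnorm(20, 50, 0.01), 10, 2))
  rownames(co2) <- paste0("s", 1:20)
  res2 <- wilksLambda(embedding(co2), rep(c("a", "b"), each = 10))
  expect_lt(res2@wilksLambda, 1e-6)
  expect_lt(res2@pValue, 1e-20)
})

test_that("Wilks' lambda is invariant under invertible affine maps", {
  set.seed(21)
  n <- 30
  g <- sample(rep(c("a", "b", "c"), each = 10))
  co <- matrix(rnorm(2 * n, sd = 3), n, 2,
               dimnames = list(paste0("s", 1:n), NULL))
  base <- wilksLambda(embedding(co), g)@wilksLambda
  for (rep in 1:20) {
    repeat {
      A <- matrix(rnorm(4), 2, 2)
      if (abs(det(A)) > 0.1) break
    }
    b <- rnorm(2)
    co2 <- sweep(co %*% A, 2, b, "+")
    rownames(co2) <- rownames(co)
    expect_equal(wilksLambda(embedding(co2), g)@wilksLambda, base,
                 tolerance = 1e-8)
  }
})

test_that("PC1 ANOVA score equals the textbook F-test and saturates
           sensibly", {
  # hand-computed one-way ANOVA for (1, 1.1, 5, 5.1) in groups (a,a,b,b)
  pc1 <- c(1, 1.1, 5, 5.1)
  g <- c("a", "a", "b", "b")
  ma <- mean(pc1[1:2]); mb <- mean(pc1[3:4]); mm <- mean(pc1)
  ssb <- 2 * (ma - mm)^2 + 2 * (mb - mm)^2
  ssw <- sum((pc1[1:2] - ma)^2) + sum((pc1[3:4] - mb)^2)
  Fstat <- (ssb / 1) / (ssw / 2)
  pOracle <- stats::pf(Fstat, 1, 2, lower.tail = FALSE)
  co <- cbind(pc1, 0); rownames(co) <- paste0("s", 1:4)
  expect_equal(pc1AnovaScore(embedding(co), g), -log10(pOracle),
               tolerance = 1e-10)

  # group means forced equal with within-group noise: score near 0
  set.seed(5)
  g2 <- rep(c("a", "b"), 20)
  pc <- rnorm(40)
  pc[g2 == "a"] <- pc[g2 == "a"] - mean(pc[g2 == "a"])
  pc[g2 == "b"] <- pc[g2 == "b"] - mean(pc[g2 == "b"])
  co2 <- cbind(pc, 0); rownames(co2) <- paste0("s", 1:40)
  expect_lt(pc1AnovaScore(embedding(co2), g2), 0.01)

  # (near-)zero within-group variance with distinct means: the score
  # saturates, capped at 320 when the p-value underflows entirely
  co3 <- cbind(rep(c(0, 1), each = 5), 0)
  rownames(co3) <- paste0("s", 1:10)
  sat <- suppressWarnings(   # base anova warns on the perfect fit
    pc1AnovaScore(embedding(co3), rep(c("a", "b"), each = 5)))
  expect_gte(sat, 100)
  expect_lte(sat, 320)
})

test_that("PC1 ANOVA scores agree with stats::anova on random instances
           and grow with the effect size", {
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(8:40, 1)
    g <- factor(sample(rep(c("a", "b", "c"), length.out = n)))
    if (any(table(g) < 2)) next
    pc1 <- rnorm(n) + as.integer(g) * runif(1, 0, 2)
    co <- cbind(pc1, rnorm(n)); rownames(co) <- paste0("s", 1:n)
    pOracle <- anova(lm(pc1 ~ g))[["Pr(>F)"]][1]
    expect_equal(pc1AnovaScore(embedding(co), g),
                 min(-log10(pOracle), 320), tolerance = 1e-10)
  }

  # fixed n and noise, growing group shift -> non-decreasing score
  set.seed(15)
  noise <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  scores <- sapply(c(0.5, 2, 8), function(eff) {
    pc1 <- noise + ifelse(g == "b", eff, 0)
    co <- cbind(pc1, 0); rownames(co) <- paste0("s", 1:20)
    pc1AnovaScore(embedding(co), g)
  })
  expect_true(all(diff(scores) > 0))
})

test_that("label-permutation null p-values are uniform for a
           structureless cloud", {
  set.seed(77)
  n <- 40
  co <- matrix(rnorm(2 * n), n, 2, dimnames = list(paste0("s", 1:n), NULL))
  emb <- embedding(co)
  p <- replicate(400, wilksLambda(emb, sample(rep(c("a", "b"), n / 2)))@pValue)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
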