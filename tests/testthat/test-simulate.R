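smallDs3 <- function(...) {
  simPreset("ds3_two_proteome", nPlexes = 1,
            proteinsPerSpecies = c(human = 20, yeast = 20),
            psmsPerProtein = 3, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  cfg <- smallDs3()
  a <- simulatePlexes(cfg, seed = 10)
  b <- simulatePlexes(cfg, seed = 10)
  expect_identical(a$psm, b$psm)
  expect_identical(a$truth, b$truth)
  expect_identical(designTable(a$design), designTable(b$design))
  c <- simulatePlexes(cfg, seed = 11)
  expect_false(identical(a$psm, c$psm))
})

test_that("the degenerate forward model reproduces configured ratios
           exactly", {
  cfg <- smallDs3(noiseSigma = 0, psmSigma = 0, contaminationMax = 0)
  sim <- simulatePlexes(cfg, seed = 4)
  Y <- as.matrix(sim$psm[grep("^Reporter intensity ",
                              names(sim$psm))])
  # observed equals expected equals true pre-leakage (identity mixing)
  expect_equal(unname(Y), unname(expectedObserved(sim)), tolerance = 1e-12)
  expect_equal(unname(expectedObserved(sim)), unname(sim$truth$trueX))

  # per-PSM channel ratios equal configured amount ratios
  sp <- sim$truth$psm$species
  comp <- cfg$composition
  yAmt <- comp$yeast
  i <- which(sp == "yeast")[1]
  expect_equal(unname(Y[i, ] / sum(Y[i, comp$role == "sample"])),
               unname(yAmt / sum(yAmt[comp$role == "sample"])),
               tolerance = 1e-12)
})

test_that("ds presets encode the published benchmark designs", {
  # two-proteome series: yeast 1/1.75/3/5.2/9 vs 3.9 in the reference,
  # constant human 50
  cfg3 <- simPreset("ds3_two_proteome")
  comp <- cfg3$composition
  expect_equal(sort(unique(comp$yeast[comp$role == "sample"])),
               c(1, 1.75, 3, 5.2, 9))
  expect_equal(comp$yeast[comp$role == "reference"], 3.9)
  expect_true(all(comp$human == 50))
  sim <- simulatePlexes(smallDs3(), seed = 1)
  tr <- sim$truth$ratios
  yr <- tr[tr$species == "yeast" & grepl("^y9", tr$sample), ]
  expect_equal(unique(log2(yr$ratioReference)), log2(9 / 3.9))
  hr <- tr[tr$species == "human", ]
  expect_true(all(hr$ratioReference == 1))

  # carrier design: ratio to single-cell channel, 127C empty
  cfg1 <- simPreset("ds1_carrier", carrierRatio = 98)
  c1 <- cfg1$composition
  expect_equal(c1$role[c1$channel == "126"], "carrier")
  expect_equal(c1$role[c1$channel == "127C"], "empty")
  sampHuman <- c1$human[c1$role == "sample"]
  expect_equal(c1$human[c1$role == "carrier"], 98 * mean(sampHuman))
  expect_false(is.null(cfg1$correctionFactors))

  # interference benchmark: human:yeast 100:0/6/9/12, channel 126 empty
  cfg5 <- simPreset("ds5_phospho_ratios")
  c5 <- cfg5$composition
  expect_equal(c5$role[c5$channel == "126"], "empty")
  expect_equal(sort(unique(c5$yeast[c5$role == "sample"])), c(0, 6, 9, 12))
  expect_true(all(c5$human[c5$role == "sample"] == 100))
  expect_gt(cfg5$contaminationMax, 0)
})

test_that("contamination writes the true PIF and compresses ratios
           toward the background profile", {
  cfg <- smallDs3(contaminationMax = 0.5, noiseSigma = 0, psmSigma = 0)
  sim <- simulatePlexes(cfg, seed = 6)
  expect_true(all(sim$psm$PIF >= 0.5 & sim$psm$PIF <= 1))
  expect_equal(sim$psm$PIF, sim$truth$psm$pif)

  # closed-form mixture arithmetic: a fully contaminated yeast PSM's
  # expected ratio collapses toward the human (flat) pattern
  Ey <- expectedObserved(sim)
  f <- 1 - sim$truth$psm$pif
  yeastRows <- which(sim$truth$psm$species == "yeast")
  comp <- cfg$composition
  sIdx <- which(comp$role == "sample")
  trueRatio <- comp$yeast[sIdx[10]] / comp$yeast[sIdx[1]]
  obsRatio <- Ey[yeastRows, sIdx[10]] / Ey[yeastRows, sIdx[1]]
  fy <- f[yeastRows]
  expect_true(all(obsRatio <= trueRatio + 1e-9))
  expect_true(all(obsRatio[fy > 0] < trueRatio))
  # and the more contaminated, the stronger the compression
  expect_true(all(diff(obsRatio[order(fy)]) < 1e-9))
})

test_that("batch factors scale whole plexes and empty channels carry
           only leakage", {
  cfg <- simPreset("ds3_two_proteome", nPlexes = 2,
                   proteinsPerSpecies = c(human = 10, yeast = 10),
                   psmsPerProtein = 3, psmSigma = 0, noiseSigma = 0,
                   batchFactors = c(1, 8))
  sim <- simulatePlexes(cfg, seed = 9)
  Y <- as.matrix(sim$psm[grep("^Reporter intensity ", names(sim$psm))])
  m1 <- median(rowSums(Y[sim$psm$Plex == "plex1", ]))
  m2 <- median(rowSums(Y[sim$psm$Plex == "plex2", ]))
  expect_gt(m2 / m1, 2)   # same abundances, 8x plex scale

  # identity impurities + zero amounts: empty channel is exactly zero
  cfg5 <- simPreset("ds5_phospho_ratios",
                    proteinsPerSpecies = c(human = 10, yeast = 10),
                    psmsPerProtein = 2, correctionFactors = NULL)
  sim5 <- simulatePlexes(cfg5, seed = 2)
  expect_true(all(sim5$psm[["Reporter intensity 1"]] == 0))
})

test_that("invalid configurations are rejected at construction", {
  cfg <- smallDs3()
  comp <- cfg$composition
  badComp <- comp; badComp$yeast[1] <- -1
  expect_error(simConfig(cfg$labelSet, badComp,
                         proteinsPerSpecies = c(human = 5, yeast = 5)),
               ">= 0")
  expect_error(simConfig(cfg$labelSet, comp[-1, ],
                         proteinsPerSpecies = c(human = 5, yeast = 5)),
               "every channel")
  expect_error(simConfig(cfg$labelSet, comp,
                         proteinsPerSpecies = c(human = 5, yeast = 5),
                         nPlexes = 2, batchFactors = 1))
  expect_error(simConfig(cfg$labelSet, comp,
                         proteinsPerSpecies = c(bogus = 5)),
               "named by the composition's species")
})
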