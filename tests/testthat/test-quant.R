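# 4-channel design: sample, sample, reference, carrier
quadDesign <- function() {
  ls4 <- labelSet(c("c1", "c2", "c3", "c4"))
  experimentalDesign(ls4, data.frame(
    plex = "plex1", channel = c("c1", "c2", "c3", "c4"),
    role = c("sample", "sample", "reference", "carrier"),
    sample = c("s1", "s2", NA, NA),
    group = c("g1", "g2", NA, NA)))
}

test_that("reference intensity sums the right channels per mode", {
  ls10 <- labelSet("TMT10")
  tab <- data.frame(plex = "plex1", channel = channelNames(ls10),
                    role = c(rep("sample", 8), "reference", "reference"),
                    sample = c(paste0("s", 1:8), NA, NA),
                    group = c(rep("g", 8), NA, NA))
  des <- experimentalDesign(ls10, tab)
  y <- c(10, 20, 30, 40, 50, 60, 70, 80, 100, 140)
  psm <- tinyPSM(rbind(y), "P1")
  expect_equal(referenceIntensity(psm, des, "reference"), 240)
  expect_equal(referenceIntensity(psm, des, "all_sample_sum"), sum(y[1:8]))

  # carrier and empty channels contribute in neither mode
  des4 <- quadDesign()
  psm4 <- tinyPSM(rbind(c(10, 20, 30, 1e6)), "P1")
  expect_equal(referenceIntensity(psm4, des4, "reference"), 30)
  expect_equal(referenceIntensity(psm4, des4, "all_sample_sum"), 30)

  noRef <- tinyDesign(roles = c("sample", "sample"))
  expect_error(referenceIntensity(psm, noRef, "reference"),
               "requires at least one reference channel")
})

test_that("PIF computation and filters follow the documented semantics", {
  expect_equal(computePIF(90, c(90, 10)), 0.9)
  expect_equal(computePIF(c(50, 30), c(50, 30, 20)), 0.8)
  expect_equal(computePIF(c(5, 5), c(5, 5)), 1)
  expect_error(computePIF(numeric(), numeric()), "empty")

  psm <- tinyPSM(matrix(1, 4, 2), paste0("P", 1:4),
                 pif = c(0.5, 0.8, 1.0, NA))
  expect_equal(nrow(pifFilter(psm, 0.75)), 2L)
  expect_equal(nrow(pifFilter(psm, 0)), 4L)      # missing kept at 0 only
  expect_equal(nrow(pifFilter(psm, 0.4)), 3L)

  psm[["Base peak ratio"]] <- c(0.1, 0.5, 2, NA)
  expect_equal(nrow(basePeakRatioFilter(psm, 0.3)), 2L)
  expect_equal(nrow(basePeakRatioFilter(psm, 0)), 4L)
  # filters intersect
  expect_equal(nrow(basePeakRatioFilter(pifFilter(psm, 0.75), 0.3)), 2L)
})

test_that("summed roll-up sums PSMs and fractions, never fabricating
           zeros for absent groups", {
  des <- tinyDesign()
  psm <- tinyPSM(rbind(c(10, 1), c(30, 2)), c("P1", "P1"))
  qm <- aggregateSum(psm, des)
  expect_s4_class(qm, "QuantMatrix")
  expect_equal(quantValues(qm)["P1", ], c(s1_plex1 = 40, s2_plex1 = 3))
  expect_equal(psmCounts(qm)["P1", 1], 2L)
  expect_equal(quantKind(qm), "summed_raw")

  # two fractions sharing the experiment/plex key collapse to one column
  frac <- rbind(psm, psm)
  expect_equal(quantValues(aggregateSum(frac, des))["P1", 1], 80)

  # group filtered out of a plex -> NA cells, not zero
  des2 <- experimentalDesign(labelSet(c("A", "B")), data.frame(
    plex = c("plex1", "plex1", "plex2", "plex2"),
    channel = c("A", "B", "A", "B"), role = "sample",
    sample = c("s1", "s2", "s3", "s4"), group = "g"))
  psm2 <- tinyPSM(rbind(c(5, 6)), "P9", plex = "plex1")
  V <- quantValues(aggregateSum(psm2, des2))
  expect_equal(unname(V["P9", c("s1", "s2")]), c(5, 6))
  expect_true(all(is.na(V["P9", c("s3", "s4")])))
})

test_that("weighted-median normalization reduces correctly in the small", {
  des <- quadDesign()
  psm <- tinyPSM(rbind(c(50, 20, 100, 999)), "P1")
  V <- quantValues(wmNormalize(psm, des, wmConfig("reference")))
  expect_equal(V["P1", ], c(s1 = 0.5, s2 = 0.2))
  V2 <- quantValues(wmNormalize(psm, des, wmConfig("all_sample_sum")))
  expect_equal(V2["P1", ], c(s1 = 50 / 70, s2 = 20 / 70))

  # zero sample or reference intensity: PSM skipped for that cell
  psm0 <- tinyPSM(rbind(c(0, 20, 100, 0), c(60, 30, 0, 0)), c("P1", "P1"))
  V0 <- quantValues(wmNormalize(psm0, des, wmConfig("reference")))
  expect_true(is.na(V0["P1", "s1"]))      # only PSM with s1>0 has ref 0
  expect_equal(V0["P1", "s2"], 0.2)

  # minPSMs gates cells
  cfgMin <- wmConfig("reference", minPSMs = 2)
  expect_true(all(is.na(quantValues(wmNormalize(psm, des, cfgMin)))))
})

test_that("weight exponent 0 reproduces the unweighted median and the
           exponent weights follow precursor x fill time", {
  des <- tinyDesign(roles = c("sample", "reference"),
                    channels = c("A", "B"))
  Y <- cbind(c(10, 20, 80), rep(100, 3))
  psm <- tinyPSM(Y, rep("P1", 3), precursor = c(1, 1, 50), fill = 1)
  v0 <- quantValues(wmNormalize(psm, des,
                                wmConfig("reference", weightExponent = 0)))
  expect_equal(unname(v0["P1", 1]), median(c(0.1, 0.2, 0.8)))
  v1 <- quantValues(wmNormalize(psm, des,
                                wmConfig("reference", weightExponent = 1)))
  expect_equal(unname(v1["P1", 1]), 0.8)  # heavy PSM dominates
})

test_that("wm normalization is invariant to plex-wide scaling and to PSM
           row order, and commutes with PIF filtering", {
  set.seed(1)
  sim <- simulatePlexes(simPreset("ds3_two_proteome", nPlexes = 2,
                                  proteinsPerSpecies = c(human = 25,
                                                         yeast = 25),
                                  psmsPerProtein = 3,
                                  contaminationMax = 0.3), seed = 2)
  psm <- sim$psm
  cfg <- wmConfig("all_sample_sum")
  base <- quantValues(wmNormalize(psm, sim$design, cfg))

  # scale one plex by c > 0: unchanged (both modes)
  scaled <- psm
  ri <- grep("^Reporter intensity ", names(psm), value = TRUE)
  rows <- scaled$Plex == "plex2"
  scaled[rows, ri] <- scaled[rows, ri] * 17.3
  expect_equal(quantValues(wmNormalize(scaled, sim$design, cfg)), base,
               tolerance = 1e-12)
  cfgR <- wmConfig("reference")
  expect_equal(quantValues(wmNormalize(scaled, sim$design, cfgR)),
               quantValues(wmNormalize(psm, sim$design, cfgR)),
               tolerance = 1e-12)

  # permuting PSM rows changes nothing
  perm <- psm[sample(nrow(psm)), ]
  expect_equal(quantValues(wmNormalize(perm, sim$design, cfg)), base)

  # pif filter then normalize == normalize with the threshold configured
  th <- 0.85
  a <- quantValues(wmNormalize(pifFilter(psm, th), sim$design, cfg))
  cfgT <- cfg; cfgT$pifThreshold <- th
  b <- quantValues(wmNormalize(psm, sim$design, cfgT))
  expect_identical(a, b)
})
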