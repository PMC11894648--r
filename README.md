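# plexquant

Reporter-ion quantification for isobaric labeling (TMT / iTRAQ / TMTpro)
proteomics, at the level where it actually happens: the peptide-spectrum
match (PSM).  The package is for proteomics data analysts who have
PSM-level reporter intensities (MaxQuant `msms.txt`-style tables) for a
multi-plex experiment and need protein-group quantities that are free of
tag impurity leakage and of between-plex batch effects — plus the
diagnostics to prove it.

## What it computes

**Impurity correction.** Each isobaric tag batch leaks a few percent of
its reporter signal into neighboring channels.  With observed
intensities *y*, corrected intensities *x* and the vendor mixing matrix
*A* (row *i* = distribution of channel *i*'s true signal, rows
normalized to 1), the observed vector is *y = Aᵀx*.  `correctImpurities()`
removes zero channels from the system, solves the reduced system by LU
factorization, and clamps negative components to zero.  Templates are
TSV files with *named* destination channels, so C-type vs N-type
leakage (e.g. TMTpro 126 → 127C *and* 127N) is unambiguous.

**Weighted-median normalization.**  For protein group *g* and sample
channel *c*, the value is the weighted median over the group's PSMs of
the within-spectrum ratios

    r_i = y_ic / ref_i ,   w_i = (precursor intensity × fill time)^α

with `ref_i` either the summed reference channels (`mode="reference"`)
or the sum of all sample channels (`mode="all_sample_sum"` — no
reference channels needed).  Within-spectrum ratios cancel any
plex-wide scale factor, which is what removes batch effects.

**Batch-effect evaluation.**  `pcaEmbed()` (deterministic 2-D PCA),
`pc1AnovaScore()` (−log₁₀ one-way ANOVA p of a grouping on PC1) and
`wilksLambda()` (MANOVA Λ = det W / det(W+B) with a Bartlett chi-square
p-value) quantify whether samples cluster by plex (batch) or by
biology.

**Synthetic benchmarks.**  `simPreset()` / `simulatePlexes()` generate
multi-plex PSM tables with full ground truth emulating three published
benchmark designs: a TMTpro single-cell carrier series (`ds1_carrier`,
carrier 14–434×, empty 127C), a TMT11 two-proteome dilution series
(`ds3_two_proteome`, yeast 1/1.75/3/5.2/9 vs a 3.9 reference on a
constant human background), and a TMTpro co-isolation/PIF benchmark
(`ds5_phospho_ratios`, human:yeast 100:0/6/9/12 with channel 126
empty).

## Worked example

Simulate a two-plex two-proteome dilution series, normalize without
using the reference channel, and check which grouping dominates:

```r
library(plexquant)

cfg <- simPreset("ds3_two_proteome", nPlexes = 2)
sim <- simulatePlexes(cfg, seed = 42)
qm  <- wmNormalize(sim$psm, sim$design, wmConfig("all_sample_sum"))
qm
#> QuantMatrix [wm_normalized]: 400 protein groups x 20 samples
#>   missing cells: 50

emb <- pcaEmbed(qm)
si  <- sampleInfo(sim$design)
wilksLambda(emb, si$plex, grouping = "plex")
#> MANOVA of grouping 'plex' (2 groups, 20 samples)
#>   Wilks' lambda = 0.97732, p = 0.82281
wilksLambda(emb, si$group, grouping = "group")
#> MANOVA of grouping 'group' (5 groups, 20 samples)
#>   Wilks' lambda = 6.6719e-05, p = 3.1199e-28
pc1AnovaScore(emb, si$plex)    # 0.004
pc1AnovaScore(emb, si$group)   # 29.37
```

Read: after weighted-median normalization the plex (batch) grouping
explains essentially nothing (Λ ≈ 0.98, PC1 score ≈ 0) while the
biological dilution groups separate decisively (Λ ≈ 7e-05, PC1 score
≈ 29).  On the unnormalized summed matrix the pattern inverts — run
`pcaEmbed(aggregateSum(sim$psm, sim$design))` to see it.

Impurity correction with the bundled synthetic TMTpro template:

```r
ls16 <- labelSet("TMTpro16")
tf <- system.file("extdata", "tmtpro16_impurities_synthetic.tsv",
                  package = "plexquant")
M <- buildMixingMatrix(ls16, readCorrectionTemplate(tf, ls16))
M
#> MixingMatrix (16 x 16) for TMTpro16
#>   total off-diagonal leakage: 1.036
psmCorrected <- correctPSMTable(sim$psm, M)  # adds "Reporter intensity corrected k"
```

## Command line

A thin wrapper over the same functions ships at
`inst/cli/plexquant.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","plexquant.R",package="plexquant"))')" \
  simulate --preset ds3_two_proteome --plexes 2 --seed 42 --out-dir sim/
# then: correct / filter / sum / normalize / evaluate / pipeline
```

Every stage logs input/output record counts to stderr and produces
byte-identical files to the equivalent library calls.

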