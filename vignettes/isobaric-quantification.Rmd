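---
title: "Isobaric labeling quantification: impurity correction, weighted-median normalization and batch-effect evaluation"
author: "plexquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isobaric labeling quantification with plexquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexquant)
```

# The problem

Isobaric labeling (TMT, iTRAQ, TMTpro) multiplexes up to 16 or more
samples into one LC-MS/MS run: every sample's peptides carry a tag of
identical total mass whose low-mass reporter fragment differs, so one
MS/MS spectrum quantifies all channels of a plex at once.  Two
systematic distortions stand between the raw reporter intensities and
usable protein quantities:

* **isotopic impurity leakage** — each tag batch contains isotopologues
  that shift a few percent of a channel's signal into neighboring
  channels.  In carrier/single-cell designs, where one channel carries
  hundreds of times the material of the others, even sub-percent
  leakage swamps the neighbor channels;
* **batch effects across plexes** — experiments larger than one plex
  differ in global intensity scale and sample handling per plex, so
  unnormalized protein intensities cluster by plex, not by biology.

`plexquant` implements the PSM-level quantification core that addresses
both: impurity correction by inverting the mixing matrix, and
weighted-median (WM) normalization of sample/reference ratios, plus the
diagnostics (PCA, PC1 ANOVA scores, Wilks' lambda MANOVA) used to judge
whether the batch effect is gone, and a synthetic multi-plex generator
that makes the whole pipeline testable without any external data.

# Impurity correction

Let $y_1,\dots,y_n$ be the measured reporter intensities of one
spectrum and $x_1,\dots,x_n$ the unknown corrected intensities.  The
tag vendor's certificate gives a mixing matrix $A$ whose row $i$ holds
the distribution of channel $i$'s true signal over observed channels;
rows are normalized to 1.  With that row convention the observed vector
is $y = A^T x$.  (The alternative orientation $y = Ax$ is inconsistent
with rows being "where a label's signal goes"; this is the one genuine
ambiguity in the formulation and the package resolves it this way.)

`correctImpurities()` proceeds per spectrum:

1. channels with $y_i = 0$ exactly are removed from $y$ and from both
   rows and columns of $A$ — only exact zeros, tiny positive
   intensities are kept;
2. the reduced square system is solved by dense LU factorization;
3. negative solution components are clamped to 0;
4. removed channels report $x_i = 0$.

Two choices are deliberately conservative where the behavior of other
software is unspecified:

* the reduced sub-matrix is solved **as-is**, without re-normalizing
  its rows after the removal of zero channels;
* a singular reduced system (essentially impossible for physical,
  diagonally dominant templates) passes the raw values through
  unchanged with a warning, so no spectrum is silently lost.

Correction-factor templates are TSV files
(`source  destination  percent`) whose destinations are *named
channels*, not ±1 mass offsets.  Naming destinations is what makes
C-type versus N-type leakage unambiguous: for TMTpro, channel 126 leaks
into both 127C ($^{13}$C impurity) and 127N ($^{15}$N impurity), which
an offset-based format cannot express.  The file
`inst/extdata/tmtpro16_impurities_synthetic.tsv` ships a synthetic
template with vendor-like magnitudes (6–7% +1, ~1% −1) for tests and
simulations; it is not a measured certificate.

# Weighted-median normalization

For protein group $g$ and sample channel $c$, the normalized value is
the weighted median over the group's PSMs of the ratios

$$r_i = \frac{y_{ic}}{\text{ref}_i}, \qquad
  w_i = (\text{precursor intensity}_i \times \text{fill time}_i)^{\alpha}$$

where $\text{ref}_i$ is, per PSM, either the summed reference-channel
intensity (`mode = "reference"`) or the sum over all sample channels
(`mode = "all_sample_sum"`).  Carrier and empty channels contribute to
neither.  The weight is proportional to the number of ions actually
fragmented, so ratios backed by many ions dominate; the exponent
$\alpha$ ("isobaric weight exponent", default 1, $\alpha = 0$ gives
plain medians) tempers that dominance.  No default for $\alpha$ is
established in the literature the package follows; 1.0 is the neutral
choice of using the weights as they are.

Because each ratio is formed *within one spectrum*, any plex-wide
multiplicative factor cancels exactly — that is the whole mechanism of
batch-effect removal, and `wmNormalize()` is provably invariant to
scaling any plex by any $c > 0$ (a property the test suite checks
directly).

Numerical conventions, fixed where upstream descriptions are silent:

* **tie rule**: the weighted median sorts values ascending and returns
  the first value whose cumulative weight reaches half the total; if
  the cumulative weight hits exactly half, the midpoint of that value
  and the next distinct value is returned.  With equal weights this
  reduces to the ordinary even-count median.  Any returned value
  minimizes $\sum_i w_i |v_i - m|$.
* **zeros**: a PSM contributes to a cell only when both the sample and
  the reference intensity are positive — a zero denominator is
  undefined and zero numerators would collapse medians to 0 in sparse
  channels.
* **missing weight inputs**: an absent precursor intensity or fill
  time contributes a factor 1 instead of discarding the PSM.
* **output scale**: cells are the weighted-median *ratios* themselves.
  Whether downstream tools prefer ratios or rescaled intensity-like
  numbers is presentational; the ratio is the quantity the method
  defines, and intensity-scale output can be recovered by multiplying
  with the group's summed reference intensity.
* **minPSMs** defaults to 1 (no minimum support is imposed by the
  method itself); raise it to suppress single-PSM cells.

`aggregateSum()` provides the unnormalized companion: per group and
sample channel, the plain sum of reporter intensities over all PSMs,
with fractions combined through the shared plex/experiment identifier,
and *missing* (not zero) cells for groups absent from a plex.

Quantification filters mirror the MS2-level filters of standard
pipelines: `pifFilter()` keeps PSMs whose precursor intensity fraction
(the fraction of isolation-window intensity belonging to the targeted
precursor, `computePIF()`) reaches a threshold, and
`basePeakRatioFilter()` does the same for the base peak ratio.  PSMs
with a missing value pass only at threshold 0, so threshold 0 is the
identity.

# Batch-effect evaluation

`pcaEmbed()` projects samples onto the first two principal components
of the log2-transformed, per-protein-centered samples × proteins
matrix.  Only proteins quantified in every sample enter (imputation is
deliberately excluded — it would blur exactly the effect being
measured), and the component sign is fixed by making each component's
largest-magnitude loading positive, so embeddings are bit-reproducible.
Nonlinear embedders (t-SNE, UMAP) are consumed as externally computed
coordinate files via `readEmbedding()`; with the small sample counts
typical of benchmark designs a linear projection is sufficient, and
their internals are out of scope here.

Two scores quantify which grouping dominates an embedding:

* `pc1AnovaScore()` — $-\log_{10}$ of the one-way ANOVA p-value of the
  grouping on PC1, capped at 320 when the p-value underflows;
* `wilksLambda()` — MANOVA on both dimensions:
  $\Lambda = \det(W)/\det(W+B)$ with pooled within-group scatter $W$
  and between-group scatter $B$; $\Lambda \to 1$ means no separation,
  $\Lambda \to 0$ strong separation.  The p-value uses Bartlett's
  chi-square approximation
  $-(N - 1 - (d+g)/2)\ln\Lambda \sim \chi^2_{d(g-1)}$ with $d = 2$,
  chosen over Rao's F for its simplicity at $d = 2$; a singular $W$
  receives a ridge of $10^{-12}\,\mathrm{tr}(W)$ and the result is
  flagged.  $\Lambda$ is invariant under any invertible affine map of
  the coordinates, which the tests verify against random affine
  transforms and an independent `stats::manova()` oracle.

The expected pattern, which the bundled simulations reproduce: on
*unnormalized summed* data the plex grouping dominates PC1 and the
biological grouping does not; after WM normalization the plex score
collapses (the scale factors cancel) and the biological grouping
separates strongly — and ignoring reference channels altogether tends
to separate the biology at least as well as using them, since the
all-sample-sum denominator averages channel noise that a single
reference channel injects into every ratio.

# The synthetic benchmark generator

`simulatePlexes()` draws PSM tables with complete ground truth from a
forward model: per-protein lognormal base abundance
($\sigma = 2$ natural-log units, a standard stand-in for proteome
dynamic range), true channel intensity = abundance × configured
species amount × plex batch factor × lognormal per-PSM ionization
scale, optional co-isolation contamination (a background-proteome
pattern added at relative amount $f/(1-f)$, with the record's PIF set
to $1-f$), impurity mixing $y = A^T x$, and multiplicative lognormal
channel noise.  Precursor intensities follow the PSM's summed signal
times lognormal noise; fill times are uniform in 5–100 ms.  The same
configuration and seed give byte-identical tables.

Three presets emulate published benchmark designs:

* `ds3_two_proteome` — TMT 11-plex dilution series: constant 50 units
  human with yeast at 1/1.75/3/5.2/9 units, two replicates per plex
  plus a reference channel (50 human + 3.9 yeast), three plexes by
  default.  Per-protein defaults: 200 proteins/species, Poisson mean 5
  PSMs/protein/plex, channel noise $\sigma = 0.1$.
* `ds1_carrier` — TMTpro 16-plex single-cell carrier design: channel
  126 carries a bulk 2:1:1 human:ecoli:yeast proteome at 14–434× the
  single-cell amount, 127C is empty, the remaining 14 channels are
  single-cell samples, and the synthetic TMTpro impurity template is
  forward-applied.  The published design varies the species mix per
  channel; the preset uses one uniform 2:1:1 composition for all
  sample channels, which preserves the mechanism under study (carrier
  leakage into 127N) without per-channel bookkeeping.
* `ds5_phospho_ratios` — TMTpro 16-plex interference benchmark:
  constant human background (100 units) with yeast at 0/6/9/12 units
  in triplicate, channel 126 empty, contamination fractions uniform on
  [0, 0.6] drawn per PSM, noise $\sigma = 0.05$.  The co-isolated
  background follows the human (constant) profile — exactly what makes
  interference compress yeast ratios toward zero and lets a PIF sweep
  (`pifSweep()`) recover them as the threshold tightens.

What the generator does *not* emulate: peptide sequences and spectra,
retention-time structure, missing-value mechanisms other than Poisson
PSM sampling, counting (shot) noise, isotope-pattern physics of the
labels, and identification errors.  Passing tests therefore demonstrate
the correctness and the qualitative behavior of the quantification
algebra under a realistic intensity model — not end-to-end performance
on real raw data, which additionally depends on the identification
stack in front of this package.

# Problem sizes and determinism

The shipped tests and the acceptance script run the presets at their
default sizes (400–600 proteins, ~2,000–5,000 PSMs, one to two
plexes), which this package treats as its reference desk-scale
configuration: large enough for median-based statistics to stabilize,
small enough to iterate on.  Every stochastic step takes an explicit
seed; tables are written with shortest-round-trip (`%.17g`) number
formatting so write→read cycles are bit-exact, and the CLI produces
byte-identical files to the equivalent library calls.

# Known limitations

* Ratio-scale output means proteins missing from the reference channel
  (reference mode) yield missing cells; the no-reference mode largely
  avoids this, which is one of its practical advantages.
* The Bartlett chi-square p-value is asymptotic; for very small sample
  counts per group it is approximate (the lambda itself is exact).
* Impurity correction propagates carrier-channel noise into corrected
  neighbor channels; correction removes the systematic inflation but
  cannot remove that noise floor.
* `minPSMs = 1` admits single-PSM cells, whose ratios carry no
  internal replication.
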