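---
title: "Models and methods behind spermchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spermchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermchrom)
```

## What the package computes

`spermchrom` implements a complete analysis pipeline for the multivariate
assessment of boar sperm chromatin status and motility. The experimental
layout it targets is a stud-center storage study: repeated ejaculates (AI
doses) from a panel of boars, each dose analyzed fresh (`D0`) and again
after prolonged cooled storage at 17 °C (`D11`). The measured layer is
per-cell: flow-cytometry event tables for five assay families and CASA
kinematic tracks. The derived layer is per-sample: thirteen chromatin
variables (SCSA, mBBr, CMA3, 8-oxo-dG) plus physiology and motility
summaries. The inferential layer is the statistical toolkit a study of
this design needs: factorial mixed models, FDR-masked correlation
matrices, variable clustering on Hoeffding's D, and standardized PCA with
variable contributions.

Because per-cell raw data from such studies are rarely at hand while
developing or validating an analysis, the package ships a first-class
synthetic-data generator whose ground truth is recorded per sample, so
every downstream stage can be tested for *truth recovery* rather than mere
execution.

## Per-sample statistics

**Gating.** Debris is excluded by stain negativity: an event is debris
when it is at or below the cut on every channel listed in the strategy
(single nuclear stain for most assays; the acridine-orange double-negative
rule for SCSA). The gating report accounts for every input event, and
samples with fewer than 5000 gated cells are flagged and warned about,
never silently dropped.

**SCSA.** The per-cell DNA fragmentation index is
DFI = 1000·red/(red+green); `%DFI` is the percentage of cells with DFI
strictly above 250, `SD-DFI` the sample (n−1) standard deviation of DFI,
and `%HDS` the percentage of cells whose green fluorescence exceeds a
fixed position on the channel scale, by default 65% of full scale
(0.65 × 1023 ≈ 665). We read the stainability rule as a fixed channel cut
rather than the 65th percentile of the events: a per-sample percentile
would force %HDS ≈ 35% by construction, while observed values in this
species are a few per cent.

**mBBr.** Each sample is measured as a paired split: untreated, and
DTT-reduced as a decondensed-chromatin reference. The disulfide index is
(median_DTT − median_untreated)/2. Published summaries report disulfide
levels around 20–35 while mBBr MFI sits near 1; the two cannot share one
normalization, so the package computes the disulfide index on raw channel
medians (a configurable reference defaults to 1) and normalizes the MFI to
the daily standard-sample median. Low/moderate/high fractions use fixed
channel bounds frozen in the configuration, standing in for the
reference-distribution calibration an instrument session would provide. A
negative disulfide index is returned but flagged.

**CMA3 and 8-oxo-dG.** CMA3 statistics are the composition of the
normalized median and the three-band fractions. For 8-oxo-dG both the
high-FITC percentage and the normalized FITC median are computed; the
normalized median is carried as the table variable since its published
values behave like a ratio.

**Physiology panels.** Conditional ratios are computed inside their
stated denominators — e.g. apoptotic as YO-PRO-1-positive among
PI-negative (early apoptosis among viable), superoxide-high among
H258-negative, cytoplasmic ROS as the CFDA median of H258-negative cells.
An empty denominator yields a flagged `NA`.

## Motility

Kinematic records keep the exact ratio identities LIN = 100·VSL/VCL,
STR = 100·VSL/VAP, WOB = 100·VAP/VCL. The dance measures are not defined
in most CASA manuals; we use DNC = VCL·ALH (µm²/s) and DNCm = DNC/VSL
(µm), consistent with their customary units, and exclude them from the
clustering features to avoid double counting derived quantities.
Progressive cells satisfy VCL > 25 µm/s and STR > 45%; the motile cut
defaults to VCL ≥ 10 µm/s (configurable — the threshold is a convention,
not a measurement).

Subpopulations come from a two-stage scheme standard in CASA work: k-means
with 40 groups on z-scored VCL, VSL, VAP, LIN, STR, WOB, ALH, BCF pooled
over samples, then Ward linkage on the stage-1 centroids, cut at the k in
2..6 with the best centroid silhouette. Cells inherit their group's final
label; per-sample subpopulation percentages always sum to 100. Rows are
sorted internally before k-means so the fit is invariant to input order at
a fixed seed. The expected outcome on boar data is three subpopulations —
Slow, Fast, and a fast/non-linear Hyper pattern resembling hyperactivated
cells.

## Multivariate layer

**Mixed models.** Each variable is fitted as
`value ~ day * boar + (1 | ejaculate)` by REML, with the ejaculate (the
dose measured at both days) as the random unit; ejaculate identifiers are
coded nested within boar. Day means ± SEM are estimated marginal means,
identical to raw means under perfect balance, and p-values are type-III
with Satterthwaite denominator degrees of freedom. A singular fit falls
back to the fixed-effects model with a flag.

**Correlations.** Pearson correlations per variable pair with
Benjamini–Hochberg adjustment over the upper triangle; cells with adjusted
p > 0.05 are masked. The FDR procedure is run separately per analysis day,
matching how such studies present D0 and D11.

**Hoeffding's D.** Variable clustering uses the scaled Hoeffding D, a
rank-based measure of general dependence: with midranks R, S and
bivariate ranks Q (the point itself plus points strictly smaller on both
axes, half credit for ties),

$$D = 30\,\frac{(n-2)(n-3)D_1 + D_2 - 2(n-2)D_3}
               {n(n-1)(n-2)(n-3)(n-4)},$$

D₁ = Σ(Q−1)(Q−2), D₂ = Σ(R−1)(R−2)(S−1)(S−2), D₃ = Σ(R−2)(S−2)(Q−1).
The ×30 scaling puts perfect dependence at exactly 1 (range ≈ [−0.5, 1]);
the tests verify this implementation against a brute-force evaluation of
the counting definition. Variables are agglomerated with average linkage
on 1 − D; the linkage choice is a package decision (the method is rarely
named in applied reports) and is configurable.

**PCA.** Standardized PCA via eigen-decomposition of the correlation
matrix — required for loadings to be variable–component correlations. The
contribution of variable *i* to component *j* is 100·loading²/λⱼ, so
contributions per component sum to 100 and Σᵢ loading²ᵢⱼ = λⱼ. PCA signs
being arbitrary, each component is oriented so its largest-|loading|
variable is positive. Observations are clustered by Ward linkage on the
first two PC scores with k = 2 by default, the configuration under which a
storage study separates its two analysis days along PC1. The number of
PCs fed to that clustering is not standardized in the field; two is the
default because the day contrast concentrates there, and both knobs are
exposed.

## The synthetic generator

Every assay is generated from one explicit model: events belong to a
latent state (debris, main population, fragmented tail, high-stainability
component, low/moderate/high bands, dead/apoptotic/viable classes), and
each channel is log-normal given the state — the conventional shape for
cytometry intensities; the sources never state distributions, so this is
a modeling choice, flagged as such. Values above the 10-bit full scale
(1023) are clipped, counted, and reported, as a detector would pile them
up rather than discard them.

Two design decisions matter for testing:

* **Truth is the theoretical value of each statistic, not the mixture
  weight.** Because the model is a log-normal mixture, every threshold
  probability, conditional fraction, ratio exceedance (the log-ratio of
  two log-normals is Gaussian, so P(DFI > 250) is closed form) and
  population median (one-dimensional root finding on the mixture CDF) can
  be computed exactly for the realized per-sample parameters. Recovery
  tests are therefore unbiased by construction, whatever the component
  overlap, and component spreads were chosen so that gate leakage is
  orders of magnitude below sampling error.
* **Random effects act on transformed scales.** Boar and ejaculate
  Gaussian intercepts and the fixed storage-day shift act on logits of
  proportions and logs of locations/indices, keeping every realized
  parameter in range. Baselines and day shifts default to values that
  reproduce the direction and rough size of the published D0→D11
  contrasts (e.g. %DFI 1.12→1.41, disulfide 33.3→21.3, mBBr MFI
  0.95→1.18); the effect SDs are plausible round numbers, chosen once.

CASA samples draw VCL log-normally and the VAP/VCL and VSL/VAP ratios
from Beta distributions, so VSL ≤ VAP ≤ VCL holds for every cell by
construction; the derived ratios are recomputed from the sampled
velocities and hold exactly. Component centers sit on the published
median kinematics of the Slow/Fast/Hyper subpopulations.

What the generator does **not** emulate: optics and spectral overlap,
compensation, acquisition-time drift, doublets, or the empirical shapes of
any deposited dataset. Passing truth-recovery tests therefore shows the
estimators are correct for the stated model, not that the model matches
any particular instrument's data.

## Problem sizes and numerical choices

The default emulated study is 36 boars × 3 ejaculates × 2 days = 216
samples with 5000 events per sample and assay and 500 CASA cells per
sample — the acquisition floor practitioners use. The test suite runs the
full default study once for end-to-end truth recovery; unit tests use
smaller designs. The mixed-model calibration check uses 500 null
replicates at 12 × 2 × 2, where the type-I error of the day test at
α = 0.05 should lie in (0.03, 0.07). Aggregate truth-recovery checks
compare the mean over samples of (estimate − per-sample truth) against 3
standard errors of that mean: individual samples are binomially noisy by
design, and ~3000 per-sample × per-statistic comparisons at 3 SE would be
expected to produce several false alarms for a correct implementation.

Degenerate inputs are handled explicitly rather than incidentally: empty
gates and empty event tables are errors; empty conditional denominators
are flagged `NA`s; constant variables are flagged in correlations and are
errors in PCA and clustering (named in the message); a zero VSL gives
LIN = STR = 0 with DNCm flagged missing; Hoeffding's D requires n ≥ 5 and
is `NA` with a warning for constant input; ties use midranks with half
credit.

## Limitations

* CSV is the supported event-table format; FCS files should be exported
  to CSV upstream.
* Fixed channel-scale cuts (HDS, band bounds, stain thresholds) stand in
  for per-session calibration against reference samples; analyses of real
  data are only as good as those calibration constants.
* Complete-case handling throughout the multivariate layer; no
  imputation.
* The two-stage clustering defaults (40 stage-1 groups, Ward, silhouette
  over 2..6) are a declared convention, not an inference about any
  particular historical implementation.
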