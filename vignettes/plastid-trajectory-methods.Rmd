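---
title: "Methods: quantifying chloroplast biogenesis along a leaf gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chloroplast biogenesis along a leaf gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidtraj)
```

## The model

A growing monocot leaf lays out developmental time along its axis: cells
leave the basal meristem, divide for a short while, then expand,
differentiate and green as they move tipwards. Sampling ordered segments of
one leaf therefore yields a pseudo-time course in which cellular,
organellar and molecular measurements can be aligned on a common cell-age
axis. The package models this design as 15 ordered samples: the shoot apex
(sample 1), consecutive 5-mm segments of the leaf base (samples 2–9),
discontinuous 10-mm segments further up (samples 10–14), and the mature
blade of an older leaf (sample 15).

Three quantitative corrections make the organelle trajectory interpretable.

**Position to age.** The mm-to-days relation is non-linear (cells linger
near the base). An `age_model()` couples a monotone lookup with the
observed leaf elongation rates; ages are rescaled by
`reference_rate / observed_rate` for the day in which they fall. The
packaged default lookup is a *synthetic* saturating curve calibrated to
three anchors a practitioner would recognise: cells 5–10 mm from the base
are under one day old, the basal ~15 mm span the first day, and cells at
80 mm are close to three days old. It stands in for a measured reference
gradient and should be replaced by one (`age_model(lookup = ...)`) whenever
available. The mature sample is assigned a nominal age of 8 days; it labels
the endpoint only and, being non-adjacent, its long interval contributes a
near-zero rate that never influences phase detection.

**Cell-division correction.** Each cell division halves per-cell organelle
counts on average. With no endoreduplication, every nucleus passing S phase
proceeds to mitosis, so the fraction of cells dividing across a transition
is indexed by the S-phase fraction relative to the fully cycling meristem:

$$C_i = 1 + \min\!\left(1, \frac{f_{S,i}}{f_{S,\mathrm{ref}}}\right) \in [1, 2].$$

This reproduces the two fixed points that define the rule — factor 2 when
every cell divides once (meristem to leaf base) and 1 when no cells divide
— and assumes at most one division per transition, consistent with the
short residence times of the basal samples. Two conventions were open and
are fixed as follows: the *upstream* sample's S fraction is used for each
transition (the downstream sample is already partly post-mitotic), and
fractions below a floor (default 0.01) are treated as background and
zeroed, since S-phase signals in differentiated samples are not
distinguishable from debris.

**Rates on the age axis.** Division and growth rates are log2 folds per
day:

$$r_i = \frac{\log_2(N_{i+1} C_i / N_i)}{t_{i+1} - t_i},$$

and identically for the total plastid plan area per cell
$A = N \times a$. The log2 scale makes "rounds of division" literal and
growth directly comparable; per-day (not per-mm or per-interval) units were
chosen because the biology — division frequencies, doubling times — is
narrated in time. Late negative rates are meaningful (a small, gradual
decline of plastid numbers in maturing tissue) and are never clipped.

**Phase detection.** The corrected growth-rate series is biphasic: an early
hump (proliferation plus modest enlargement of proplastids), a trough, and
a second hump (photosynthetic chloroplast expansion). `detect_phases()`
takes the interior local minimum of the (3-point moving-average smoothed)
series that separates its two largest local maxima; equal minima resolve to
the earlier index. Smoothing is on by default because single-transition
wiggles inside a hump would otherwise distract the literal
two-largest-maxima rule; the unsmoothed variant is exposed for clean
series. A monotone series raises a "no biphasic structure" error rather
than fabricating a boundary.

## Absolute qPCR quantitation

Standard curves are ordinary least squares of Cq on log10 concentration;
efficiency is `10^(-1/slope) - 1`. Technical-replicate Cq values are
averaged *before* interpolation (averaging on the cycle scale, standard
qPCR practice); quantities are rescaled by each reaction's dilution factor
(10× nuclear, 100× plastid targets). Copy number per haploid nuclear genome
follows the printed formula

$$\frac{(rbcL + ndhD + rps7/2)/3}{(TaKO1 + TaKS)/2},$$

with the inverted-repeat amplicon halved. Two interpretation points are
deliberately configuration, not code: per-amplicon mass-to-copy conversion
weights default to equal (`copies_per_pg`), because the ratio of means is
invariant to any shared constant and the amplicon lengths needed for
length-proportional weights are not part of the inputs; and no extra
hexaploidy correction is applied beyond what the primers' genome
specificity implies — the formula is implemented verbatim and the ploidy
interpretation is the user's. Plastid ribosome build-up is the plain
16S/18S ratio, identical in contract for absolute qPCR quantities and
electropherogram peak areas. Replicate aggregation averages technical
replicates within each biological replicate first, then reports mean ± SEM
across biological replicates.

## The expression map

Counts are normalised to reads per million per library. A gene is
*expressed* if all replicates reach 1 RPM at some sampling time, and
*dynamic* (a DYG) if, on replicate-averaged sample means, max RPM ≥ 5,
max/min ≥ 2, and CV ≥ 0.2. Three conventions were unstated and are fixed
here: the CV uses the sample (n−1) standard deviation over the 15 sample
means; a minimum of exactly 0 makes the fold infinite and *passes* the
criterion (a gene switching fully off/on is maximally dynamic); and
Z-scores use the same n−1 convention.

PCA operates on gene-standardised profiles with the 45 sample × replicate
libraries as observations (replicates plot as points, making their
tightness visible); the top and bottom 5% of genes by loading (ceiling, per
component) form the load-factor gene sets. Module detection is a weighted
co-expression analysis implemented directly: adjacency `|cor|^β` with
β = 14, topological-overlap similarity, average-linkage clustering, and a
*fixed-k* tree cut (default 12) rather than a dynamic cut — deterministic,
testable, and matching the expected module count; modules are relabelled by
peak timing. The network is unsigned by default; a signed option
(`(1+cor)/2)^β`) is provided because an unsigned adjacency cannot, even in
principle, separate perfectly anti-correlated profile blocks. Enrichment is
the exact hypergeometric test, reported as raw −log10 for both over- and
under-representation, with an optional Benjamini–Hochberg column off by
default to match the raw display convention.

## Regulator ranking

For each target gene (DYGs for chloroplast-targeted proteins, regulators
excluded), a random-forest regression predicts the target's profile from
all candidate regulators' profiles; a regulator's importance is its total
impurity reduction, normalised per target to sum to 1. Defaults follow the
established tree-ensemble network practice: 1000 trees and square-root
feature subsampling. Observations are the 45 Z-scored sample × replicate
values rather than 15 means — tripling the sample size and letting
replicate-level covariation contribute — with a flag to use means instead.
Constant targets yield an all-zero, flagged row rather than an error.
Regulators are sorted internally before fitting, so the ranking is
invariant to input column order; positive and negative candidate panels run
jointly and can be visualised separately.

## What the generator emulates — and what it does not

`simulate_experiment()` produces every input stream from one seed, with
per-table substreams derived by fixed offsets (adding a table never
perturbs the others; a fixed seed yields byte-identical bundles).

- *Trajectory*: organelle division rounds concentrated in the first four
  transitions and summing to 4.5 (configurable), quiescence to the trough
  (anchor transitions 3/8/11), and a −0.05 round/transition late decline;
  per-plastid area growth with a second hump producing the biphasic rate
  series. Meristem cells start at 10 proplastids of 2 µm² in 150 µm² cells;
  mature cells reach ~40 plastids of ~34 µm² in 2400 µm² cells
  (chloroplast index ~0.1 → ~0.5).
- *Cell cycle*: S-phase falls from 30% (meristem) to below the detection
  floor by sample 4, sampled as multinomial counts of ≥ 10,000 nuclei.
- *Microscopy*: 48 cells per sample across 3 replicates; lognormal
  cell-to-cell CVs of 0.30 (cell area) and 0.25 (plastid count, mean
  plastid area), mean-unbiased. These replicate-level variances are knobs,
  not claims.
- *qPCR*: five 10-fold standards from 25 to 0.0025 pg/µl, efficiency 0.95
  per amplicon, Cq noise SD 0.05 (purified standards) and 0.15 (unknowns),
  3 biological × 2 technical replicates; the planted copy-number series
  rises from 25 to ~150 per haploid genome. The 16S/18S ratio rises from
  below 1% to a plateau of ~0.3.
- *Expression*: 600 genes by default, 60% dynamic across 12 modules with
  Gaussian-bump mean profiles on the *age* axis (so age mapping is
  exercised), amplitudes ~10–200 RPM over baselines 0.5–3; flat genes
  lognormal around 8 RPM. Negative-binomial replicate noise with size 20
  (~13% CV on replicate-averaged sample means, typical of controlled
  growth-chamber RNA-seq) on top of lognormal ±20% library sizes around
  2×10⁷ reads. Planted regulator-target edges feed the regulator's
  *realised* per-library RPM into the target's mean (effect 1.5), so edges
  are recoverable from replicate covariation, not only from shared smooth
  profiles.

It does **not** emulate raw reads, flow-cytometry histograms, images,
homoeolog triads, batch effects, or compositional coupling between genes
(library sizes stand for full-transcriptome depth, so simulated RPM need
not sum to 10⁶ over the simulated subset). Passing tests therefore show
that the estimators invert the generative model they target at realistic
noise, not that they are robust to everything real data can do.

## Numerical choices and problem sizes

Degenerate inputs fail loudly with classed errors (empty samples, zero
libraries, constant profiles, monotone rate series, missing amplicons).
Ties break towards the earlier index throughout (peak samples, phase
minima). Tests run at deliberately desk-sized problems — 600 genes (20–300
where the check is analytic), 48 cells, 50/20/100-seed property suites —
chosen so the whole suite completes in about a minute while leaving the
recovery margins wide (DYG sensitivity ~100%, false admission < 2%, module
adjusted Rand ~0.87, phase boundary within ±1 sample in 100/100 seeds,
copy-number error < 5%).

Two property-scale notes. First, the variance captured by the first three
principal components depends on the planted geometry: twelve
staggered-peak modules spread variance over roughly as many directions, so
even noiseless data concentrate only ~55% in three components; the
concentration property (≥ 60%) is therefore exercised where its premise
holds — a low-rank (3-module), low-noise configuration — while the default
geometry is checked for dominance of the leading block. Second, the
Poisson-limit check of replicate noise (CV → 1/√mean as dispersion → ∞)
conditions on equal library sizes, since library-size scatter otherwise
dominates the CV of high-mean genes.

## Known limitations

- The default position/age lookup is synthetic; absolute ages (and thus
  absolute per-day rates) are only as good as the supplied calibration.
- The correction rule caps at one division per transition; a sampling
  scheme sparse enough for two divisions per interval would need a
  generalised factor.
- The fixed-k tree cut requires the expected module count; a dynamic cut
  would trade determinism for adaptivity.
- Tree-ensemble importances rank association, not causation, and share
  GENIE3's known blind spots (redundant regulators split credit).
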