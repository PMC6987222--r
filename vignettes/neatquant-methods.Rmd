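---
title: "Methods: isoform-resolved NEAT1 quantification, FISH scoring and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-resolved NEAT1 quantification, FISH scoring and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neatquant)
```

This vignette documents the models, conventions and numerical choices
behind each stage of the pipeline, what the synthetic-data generators do
and do not emulate, and the limitations a user should keep in mind.

## The two-region locus model

The *NEAT1* gene produces a short polyadenylated isoform that is a strict
5′ subsequence of the long paraspeckle-scaffolding isoform. Reads are
therefore attributed to two adjacent intervals: the **common region**
chr11:65,422,798–65,426,532 and the **NEAT1_2-specific region**
chr11:65,426,533–65,445,540 (GRCh38). Conventions:

* Coordinates are **1-based inclusive** in memory, like genome-browser
  coordinates; this reading makes the two regions exactly adjacent
  (65,426,532 + 1 = 65,426,533) and gives a common-region length of
  3,735 bp — matching the ~3.7 kb short-isoform size, which is the
  internal consistency check that fixes the convention. On-disk BED is
  0-based half-open; `rtracklayer` converts at the boundary.
* The specific-region length implied by the coordinates is 19,008 bp and
  the full locus 22,743 bp. (The long isoform is often quoted as
  "22.3 kb"; the implementation follows the coordinates.)
* A **fragment's footprint** is the outermost template span of the read
  pair, insert gap included — fragment-level counting, one unit per pair.
* A fragment overlapping both regions by ≥ 1 bp covers the internal
  junction and is **excluded** from both counts ("spanning"); a fragment
  that overhangs an *outer* locus boundary still counts toward the single
  region it overlaps, because the exclusion rule exists to prevent
  double-attribution at the junction, not to police the locus edges.
* RM~t~ in the FPKM formula is the **total mapped fragments in the
  library**, not a locus-restricted count; `quantifySample()` accepts it
  as an explicit argument (`rmTotal`) for the usual workflow where only a
  region query of the BAM is loaded.
* Non-proper pairs are counted if mapped; `requireProperPairs = TRUE`
  restricts counting to proper pairs. The permissive default reflects
  that fragment-level counting needs only a coherent template span.
* The *NEAT1_1*-eligibility filter is **strict**: a sample is retained
  only if specific-region FPKM < 1.0; FPKM exactly 1.0 is filtered out.

No CIGAR-level splice awareness is attempted: the locus is treated as
intronless, consistent with the single-exon two-interval counting scheme.
There is no EM-style isoform deconvolution — the point of the region
design is that it needs none.

## RNA-FISH quantification and the 0–3 score

The imaging pipeline is: maximum-intensity projection over z → automatic
DAPI threshold (Otsu) → hole filling → removal of components below
`minArea` (default 200 px, roughly a disc of radius 8 px at 40×) →
connected-component labels → per-nucleus mean signal intensity and focus
detection. Choices worth stating:

* **Otsu** is used as the automatic threshold; "automatic threshold" in
  common Fiji workflows defaults to Otsu-family methods, and the method is
  histogram-shape based, so segmentation is invariant to rescaling the
  DAPI channel by a positive constant (asserted in the tests). The
  projection is min-max normalized before thresholding.
* Touching nuclei are **not** split (no watershed); the generator places
  non-overlapping nuclei, and FFPE/manual workflows traced outlines
  rather than declumping. A manually traced label mask can be supplied to
  `quantifyFishStack(labels = ...)`, bypassing segmentation entirely.
* Single-plane FFPE images are the z = 1 degenerate case of the same code
  path.
* **Focus detection** (needed to operationalize "punctate nuclear
  signal") finds 8-neighbourhood local maxima above a per-nucleus robust
  background level, median + 5 × MAD of the signal pixels under the
  label, with greedy non-maximum suppression at 2 px. The robust
  statistics keep a handful of bright foci from inflating their own
  detection threshold; 5 MADs sits far above Gaussian noise excursions
  while two orders of magnitude below a typical focus amplitude.
* **The ordinal score** is defined here as an explicit, reproducible
  rule: a nucleus is positive with ≥ 1 detected focus; the sample score
  is the number of thresholds {5 %, 25 %, 60 %} that the positive-nucleus
  fraction reaches (boundaries attained upward). Expert visual scoring
  schemes are typically published as example images rather than numbers;
  a fraction-based rule with configurable thresholds
  (`ScoreCriteria()`) is one consistent operationalization, and the three
  defaults are tunable to match a given expert's calibration. Whether
  visual scoring also weighs focus size or brightness cannot be read off
  example images; prevalence alone is used here.

## ΔΔCq normalization

"Geometric mean of the reference genes" is applied where it is
well-defined: in linear relative-quantity space, i.e. the geometric mean
of 2^(−Cq), which is the **arithmetic mean of the Cq values**. (Taking a
geometric mean of Cq values directly would depend on the Cq scale's
arbitrary origin.) Technical replicates are arithmetic-mean-averaged in
Cq space before any normalization. Amplification efficiency is fixed at
2.0 (100 %); no standard-curve correction is attempted. Fold change is
2^(−ΔΔCq), so the calibrator sample is exactly 1 and
log2(fold) = −ΔΔCq to machine precision. Averaging biological replicates
before versus after the fold-change transform is left to the caller: the
function operates on whatever plate it is given.

## Association battery

* **Chi-square**: plain Pearson, all four score levels as columns, no
  Yates correction, no cell pooling. This is the variant that reproduces
  all eight published cross-tabulation p-values (0.920, 0.027, 0.156,
  0.213, 0.990, 0.131, 0.226, 0.042) from the printed counts, verified to
  3 decimals in the acceptance tests. Missing data are excluded
  per-variable (diameter n = 69, lymph node n = 71), never by deleting a
  patient from every table.
* **Rank tests** use exact computations where cheap (Mann-Whitney exact
  branch for small untied samples, validated against full enumeration in
  the tests) and tie-corrected asymptotics otherwise. Fully tied inputs,
  where the tie-corrected statistics are 0/0, are defined by convention
  as "no evidence": H = 0 / central U, p = 1.
* **Pairwise post-tests** report unadjusted p-values (the common
  presentation of figure-legend stars) alongside Holm-adjusted ones, both
  labelled, since published legends rarely state the adjustment.
* The star annotation uses inclusive boundaries:
  \*\*\*\* ≤ 0.0001 < \*\*\* ≤ 0.001 < \*\* ≤ 0.01 < \* ≤ 0.05 < ns.

The packaged `screeningCohort()` is a patient-level reconstruction from
the published variable-by-score margins. Per-variable association
statistics computed from it are identical to ones computed from the
printed tables; its joint distribution *across* variables is arbitrary
(levels assigned in blocks), so it must not be used for multivariable
modelling. The lactating-cohort fixture preserves positivity (6/8) but
not the unpublished per-sample score values.

## What the generators emulate — and what they do not

The generators exist so that every downstream operation has ground truth
to recover, at sizes chosen to mirror the study's conditions where those
are stated.

**Fragments** (`simulateLocusFragments`): placement is uniform in
transcript coordinates over the common region (short isoform) or the full
22,743 bp locus (long isoform); background fragments live on a sentinel
contig and exist only to make RM~t~ exceed the locus counts. Insert
lengths are normal (default mean 300 bp, sd 50 bp — a polyA library
convention, not a measured value), re-drawn until they fit
[read length, transcript length]. A library whose mean insert exceeds the
3,735 bp common region cannot come from the short isoform and is
rejected. Fragments serialize as coordinate-sorted, properly-paired SAM.
Not emulated: base-level sequence, sequencing error, alignment ambiguity,
splicing, coverage bias. Passing recovery tests therefore demonstrates
correctness of the counting/FPKM logic, not robustness to alignment
artifacts.

**FISH stacks** (`simulateFishStack`): DAPI discs of constant amplitude
replicated across z (default 7 slices, as in a 40× confocal z-series);
Gaussian foci (σ = 1.5 px, amplitude 200 vs noise sd 5) each on one
random z-slice, placed inside their nucleus with a best-effort ≥ 3σ
separation — resolvable puncta, which is what a maxima-based detector can
count; truth records centers, per-nucleus focus counts and the label
mask. Noise is additive Gaussian clipped at 0, the simplest model that
exercises thresholding. Not emulated: clustered/merged paraspeckles,
uneven illumination, z-attenuation, autofluorescence, touching nuclei —
so image-level results on real FFPE material are method-matched, not
bit-matched, and detector settings may need recalibration there.

**Cohorts** (`simulateCohort`): per-stratum score probability vectors;
defaults are the grade-row proportions of the published screening-cohort
table with marginals 18/23/33 of 74. **qPCR plates**
(`simulateQpcrPlate`): target Cq = calibrator Cq − true log2 fold change
+ noise; reference genes around stated means (GAPDH 18, B2M 20, RPLP0
22); a designated calibrator sample is always emitted.

All generators take a **mandatory seed** and restore the caller's RNG
state — identical parameters give bit-identical output, and no hidden
global state is touched.

## Numerical choices and degenerate inputs

* FPKM with RM~g~ = 0 is 0; RM~t~ = 0 or L = 0 raises.
* A constant DAPI projection has no Otsu threshold: empty mask + warning.
* An empty nucleus set cannot be scored (error); a single-nucleus group
  reports sd = 0 with an explicit `sd_defined = FALSE` flag.
* Contingency tables with a zero margin are rejected as degenerate.
* Spearman correlation of a constant vector is undefined: `NA` + warning.
* TIFF stacks are written as 32-bit float pages, channel-major, rescaled
  to [0, 1] with the scale stored in a JSON sidecar, so round-trips
  preserve intensities to float precision.

## Problem sizes

The validation suite runs at desk scale: 10⁴ random fragments for the
counting oracle, 5,000-fragment libraries for mixture recovery (where the
specific/common FPKM ratio is within 10 % of 1 for a pure long-isoform
library — uniform coverage cancels length), 20-nucleus 512×512 stacks for
foci recovery (within 20 % of Poisson(4) truth), 50-sample plates at Cq
noise 0.2 for fold-change recovery (MAE ≤ 0.5), and 100–200-replicate
simulations for test size and power. These sizes were chosen as the
smallest at which the stochastic tolerances are comfortably
non-flaky.

## Known limitations

* The fragment counter has no duplicate or mapping-quality filtering;
  whether the original workflow enabled such filters is unknowable from
  the text, so the default is "count everything mapped", configurable
  only via proper-pair filtering.
* Cohort-scale microarray results (e.g. subtype rankings, copy-number
  correlations) require controlled-access patient data and are outside
  what synthetic cohorts can certify; the package validates the
  *machinery* (rank tests, correlations) on synthetic data instead.
* The 0–3 score's agreement with any particular pathologist's visual
  calibration is a free parameter (the three fraction thresholds), not a
  property the synthetic tests can establish.
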