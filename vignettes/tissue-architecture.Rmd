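---
title: "Quantifying breast tissue architecture and its radiologic correlates"
author: "HistoDensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying breast tissue architecture and its radiologic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HistoDensity)
```

## The problem

Mammographic breast density — the proportion of the breast that is
fibroglandular (non-fatty) tissue — is a strong radiologic risk factor for
breast cancer, yet its histologic basis is incompletely characterized.
Modern digital-pathology segmentation produces per-pixel *tissue-class
maps* of H&E whole-slide images, labelling every pixel as epithelium,
non-fatty stroma or fat. HistoDensity takes such label maps as input and
asks two questions:

1. Which quantitative histologic features of a biopsy predict the
   radiologically measured percent fibroglandular volume (FGV), both
   global (whole breast) and localized (peri-lesional)?
2. Within strata of high and low density, which features distinguish
   invasive cancer from benign disease?

The package implements the full post-segmentation analysis: a 37-feature
architectural description of each slide, random-forest regression and
classification with impurity-based importance ranking, and ROC/AUC
inference with class-stratified percentile-bootstrap confidence intervals.
Because the motivating clinical cohorts are private, the package also
contains a first-class synthetic cohort generator whose ground truth is
known by construction, so every stage is testable end to end.

## The 37-feature vector

For a label map with pixel size $s$ µm/px, features fall into four
families (`featureFamilies()`):

**Global tissue quantities (6).** Class areas in µm² (`fat_amount`,
`stroma_amount`, `epi_amount`; pixel count × $s^2$) and the same
normalized to percent of total tissue area (labels 1–3). The three
normalized amounts sum to 100 by construction.

**Epithelial morphology (11).** Connected components of the epithelium
label under 8-connectivity form the region set $A_1,\dots,A_n$. Components
below `minRegionArea` (default 50 µm²) are treated as segmentation noise
and removed. The family comprises the region count and the
$\{$mean, median, SD, IQ, max$\}$ summaries of region area and of
eccentricity — the eccentricity of the ellipse with the same second
central moments as the pixel set ($0$ = circle; a 1-px-wide line attains
1). IQ is the interquartile range $Q_3 - Q_1$ with linear-interpolation
(type-7) quantiles; the SD of a single region is defined as 0 so one-region
slides still yield complete vectors.

**Area-Voronoi arrangement (15).** The *area-Voronoi diagram* generalizes
the point Voronoi diagram to regions: the influence zone $V_a(A_i)$ is the
set of pixels whose Euclidean distance to $A_i$'s pixel set is no larger
than to any other region's. HistoDensity restricts the zones to the tissue
mask — glass area is scanner-dependent — so the zones exactly partition
the tissue. Per region the package derives the zone area, the filling
ratio $|A_i| / |V_a(A_i)| \in (0,1]$ and the epithelium-to-non-epithelium
ratio $|A_i| / (|V_a(A_i)| - |A_i|)$ (undefined when a region fills its
zone; such values are excluded from the summaries). Each is summarized by
the same five statistics. A filling ratio near 1 means epithelium
saturates its neighborhood — the coalescent growth phenotype — while
sparse, dispersed epithelium gives ratios near the overall epithelial
fraction.

**Delaunay arrangement (5).** The Delaunay triangulation of the region
centroids defines a neighbor graph; each region's degree (incident edges)
summarizes local packing. Degenerate inputs use explicit fallbacks
(1 region → degree 0; 2 regions → 1 each; collinear centroids → chain
adjacency) so small biopsies do not error.

Slides with no retained epithelial region receive zeros for all
region-based features plus a `no_epithelium` flag, keeping model matrices
free of missing cells.

### Numerical conventions

* Distances are Euclidean between pixel centers; influence-zone ties go to
  the lowest canonical region label (regions are numbered by first pixel in
  column-major scan order). The implementation uses an exact per-region
  squared Euclidean distance transform (two-pass lower-envelope algorithm),
  so assignments equal an exhaustive per-pixel scan — the test suite
  verifies this pixel-for-pixel against a brute-force oracle.
* Delaunay edges are found with the empty-circle criterion via the
  inscribed-angle test (an edge is kept iff the largest angles subtended
  from the two sides of the segment sum to less than $\pi$), $O(n^3)$ in
  the region count; tests compare against an $O(n^4)$ circumcircle oracle.
* Coordinates are 0-based (row, col); all areas are converted to µm²
  before any aggregation so mixed-resolution cohorts are commensurable.
  Doubling the pixel size multiplies every µm² feature by exactly 4 and
  leaves all dimensionless features unchanged.
* Multi-slide patients are aggregated by the per-feature **median** across
  slides. Diagnosis aggregates as the worst across biopsies
  (non-proliferative < proliferative < atypia < in-situ < invasive).

## Modeling

`trainFgvRegressor()` fits a random forest (500 trees by default, `mtry`
$= p/3$, fixed seed) of an FGV target on the 37 features, using the
training split only, and ranks features by impurity (node-purity)
importance. `predictAndCorrelate()` reports the Spearman rank correlation
between predicted and actual FGV on held-out test patients.

`pruneCorrelated()` implements the correlated-feature sensitivity
analysis: feature pairs are visited in canonical column order and whenever
both members of a pair with $|\rho| \ge 0.85$ (Spearman) are still
retained, one is removed at random under a fixed seed. The procedure is
order- and seed-deterministic; whether the original analysis used signed
or absolute correlation is not documented, and the absolute value is the
conservative choice.

`stratifyByMedian()` splits patients at the training-split median of the
target (ties go low), and `trainCancerClassifier()` fits a random-forest
classifier of invasive carcinoma versus benign disease within a stratum.
In-situ diagnoses are excluded from training and testing before anything
is fit, the benign class pooling non-proliferative and proliferative
(± atypia) disease. The four strata (high/low × global/localized) are
modeled independently.

Nothing fitted ever sees the test split: deleting all test rows changes
neither forests, importance rankings nor cutpoints, which the test suite
asserts directly.

## Evaluation

`rocAuc()` computes the AUC as the Mann–Whitney concordance probability
with ties counted ½. `bootstrapAucCi()` resamples patients with
replacement *within each outcome class* — preserving case/control counts
in every replicate, so no replicate can be degenerate — and reads the
confidence limits from percentile order statistics (type-1 quantiles) of
the replicate AUCs; 2000 replicates by default. `compareAucBootstrap()`
compares two classifiers evaluated on disjoint patient sets: each
replicate resamples both datasets class-stratified and records the AUC
difference; the statistic $D = (\widehat{A}_a - \widehat{A}_b) /
\mathrm{sd}(\text{bootstrap differences})$ is referred to the standard
normal law, two-sided — the unpaired bootstrap scheme familiar from the
pROC package. A Monte-Carlo study in the test suite checks the interval's
coverage near its nominal level and the test's type-I error near 0.05
under an equal-AUC null. DeLong variances, partial AUC and paired-curve
comparisons are out of scope.

## The synthetic cohort generator

`generateCohort()` emulates a diagnostic biopsy study population in which
the relation between tissue composition and density is true *by
construction*, making recovery a meaningful test:

* **Composition.** Each patient draws a dense-tissue fraction
  (stroma + epithelium) around the configured mean (defaults: fat/stroma/
  epithelium = 0.62/0.28/0.10, patient SD 0.18, truncated to
  $[0.03, 0.97]$) and an epithelial fraction (SD 0.03) *independent of
  diagnosis*. Slide-level composition jitters around the patient draw
  (SD 2 pp) to exercise the median aggregation.
* **Density targets.** `global_fgv` $= 100 \times$ dense fraction $+$
  Gaussian noise (SD 5 pp by default), clipped to $[0, 100]$;
  `localized_fgv` likewise from a locally perturbed dense fraction
  (SD 4 pp). With zero noise the identity
  `global_fgv` $= 100\,(1 - \text{fat fraction})$ holds exactly.
* **Spatial organization.** Epithelial regions are elliptical blobs whose
  count is Poisson around `epiRegionCountMean` and whose total area meets
  the slide's epithelial fraction. Benign patients use *dispersed*
  placement (hard-core spacing over the whole tissue); a *clustered* mode
  places parent–offspring (Thomas-style) clumps; invasive patients use
  *coalescent* placement — near-touching packs around one or two foci,
  where influence zones collapse onto the regions (high filling ratio) and
  adjacent blobs merge into enlarged components. Since epithelial
  *fraction* distributions overlap across classes, diagnosis is encoded in
  organization, not quantity — the hypothesis the classifier analysis is
  meant to probe. Note the packing, not the merging, is what raises the
  epi-to-Voronoi ratio: a single merged mass would inherit the whole
  tissue as its zone and the ratio would fall back to the epithelial
  fraction.
* **Geometry.** The tissue mask is a superellipse sized to the configured
  glass (background) fraction; the glass fraction additionally varies
  slide to slide (SD 0.08) because real biopsy sections vary in size —
  without this, absolute µm² amounts would be exactly collinear with the
  normalized amounts, a degeneracy real slide populations do not have.
  Stroma and fat are carved from non-epithelial tissue by thresholding a
  smoothed Gaussian random field at the exact pixel quota, giving
  spatially coherent compartments.
* **Design quotas.** Diagnoses are assigned by exact quota (default 15%
  invasive, 8% in-situ, remainder split among the benign categories) and
  shuffled, rather than Bernoulli-drawn, so class counts are deterministic
  at fixed $n$; the train/test split is 69%/31% at the patient level. BMI
  is drawn negatively correlated with the dense fraction, menopausal
  status at 42% postmenopausal, for the covariate sensitivity switches.
* **Determinism.** The whole cohort — label-map bytes included — is a pure
  function of `rngSeed`.

The defaults (580 patients × 2 slides of 256×256 px at 0.5 µm/px) are the
conditions under which the package's simulation-scale checks run; they
give 400 training and 180 test patients. `epiRegionAreaMean` is not an
independent dial: the epithelial fraction and region count determine the
realized mean region area, and the field only sets the minimum blob size.
No distributional facts about real slide-level composition were available
to calibrate against, so the spread parameters are choices of plausible
heterogeneity, fixed once.

**What the generator does *not* emulate** — and hence what passing tests
cannot show about real data: segmentation error of the upstream network,
stain and scanner variation, pyramidal whole-slide formats, anatomically
realistic ductal/lobular geometry, and any real biological coupling
between composition and architecture beyond the constructions above.
Recovery results on this cohort validate the machinery, not the clinical
findings.

## Problem sizes and runtime choices

The shipped tests run the oracle-equivalence checks on twenty ≤64×64 maps
with ≤6 regions, the recovery and classification checks on the default
580-patient cohort, the bootstrap calibration on 500 Monte-Carlo binormal
datasets (150 cases/150 controls, 500 replicates each), and the
reproducibility checks on an 80-patient, 64×64 configuration — sizes
chosen so the whole suite completes in minutes on a single core while
keeping every estimate's sampling error well inside the asserted bands.
`scripts/acceptance.R` reruns the full default-size pipeline from scratch
at a caller-supplied seed.

## Known limitations

* The full public roster of the 37 features in the motivating analysis is
  not available; the roster here (6 global + 11 morphology + 15 Voronoi +
  5 Delaunay via the {mean, median, SD, IQ, max} family) contains every
  feature named in the published rankings, but individual definitions
  could differ in unpublished details. The roster is centralized in
  `featureNames()` so a corrected list can be swapped in.
* Whether regions touching the image border should be excluded from
  Voronoi statistics is unresolved; HistoDensity keeps them, which is the
  choice consistent with zones partitioning the tissue.
* Raw impurity importances from a single forest are reported (no
  repeat-averaging), and predicted probabilities are not calibrated.
* The AUC comparison assumes independent patient sets; comparing curves on
  shared patients requires a paired method not implemented here.
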