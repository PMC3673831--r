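---
title: "Quantitative CT biomarkers for COPD: methods and design notes"
author: "copdct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT biomarkers for COPD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(copdct)
```

## What this package computes

Spirometry is the reference standard for diagnosing chronic obstructive
pulmonary disease (COPD: prebronchodilator FEV1/FVC strictly below 0.70),
but lung-function testing is rarely part of CT-based lung-cancer screening.
`copdct` implements the alternative: extract three quantitative biomarkers
from the screening CT itself and combine them with demographics in logistic
diagnostic models.

* **Emphysema index (IN~-950~)** — the percentage of lung voxels on the
  *inspiratory* scan with attenuation strictly below −950 HU. Destroyed
  parenchyma holds more air and shifts the density histogram left.
* **Air trapping (E/I-ratio~MLD~)** — the ratio of expiratory to
  inspiratory mean lung density (MLD). A healthy lung densifies markedly on
  expiration (ratio well below 1); trapped gas keeps the ratio high.
* **Bronchial wall thickness (Pi10)** — per subject, ordinary least squares
  of √(wall area) on lumen perimeter over all measurable bronchial
  cross-sections; Pi10 is the fitted √WA at a 10-mm lumen perimeter, a
  caliber-standardized summary of wall thickening.

Eight nested logistic models (`model_ladder_specs()`) form the diagnostic
ladder: a demographic baseline (age, BMI, packyears, current-vs-former
smoking) plus each biomarker subset. The emphysema index enters as its
natural logarithm (its distribution is strongly right-skewed); packyears
enter untransformed; smoking status as an indicator with *former* as
reference. Each model is internally validated by bootstrap optimism
correction and uniform coefficient shrinkage, thresholded at its
optimal-accuracy cutoff, and compared by the Net Reclassification Index
(NRI).

## Synthetic data: what it emulates, and what it does not

Real screening CT and subject-level trial data cannot be redistributed, so
every stage is exercised against synthetic inputs with known ground truth.

### CT phantoms

`generate_phantom()` rasterizes a parenchyma block (a 2-voxel soft-tissue
body border around it), cylindrical airway tubes (air lumen, soft-tissue
wall) and spherical emphysema clusters into paired-phase volumes:

* **Emphysema** is placed as spheres (default radius 2 mm) by seeded
  rejection sampling inside the lung mask, and the last sphere is trimmed
  from the outside in so that the voxel count equals
  `round(fraction * n_lung)` exactly — spatially clustered like real
  centrilobular emphysema, yet exactly countable.
* **Expiration** is modeled as uniform densification: every lung voxel is
  scaled by `lung_hu_exp / lung_hu_insp`. Emphysematous voxels therefore
  stay low-attenuating on expiration (the air-trapping phenotype) and the
  phantom's true E/I-ratio equals the configured ratio exactly, independent
  of the emphysema fraction. A model in which only the healthy parenchyma
  densified would couple the true ratio to the emphysema fraction and make
  the densitometry oracle ambiguous.
* **Tube boundaries** are rasterized binarily (a voxel takes the HU of the
  compartment its center falls in). Ground truth per tube comes from closed
  forms: lumen perimeter 2πr and wall area π((r+t)² − r²).
* **Noise** is additive, independent, Gaussian per voxel — scanner noise
  correlation and reconstruction-kernel effects are *not* emulated.

Not emulated: lung texture, vasculature, respiratory deformation (both
phases share one grid, so there is no registration problem), dose and
reconstruction-kernel effects. Tests passing on phantoms therefore
demonstrate correctness of the measurement geometry and statistics, not
robustness to clinical image artifacts.

`standard_wall_phantom()` fixes a three-tube layout — (r, t) = (1.5, 0.8),
(2.5, 1.0), (4.0, 1.2) mm at 0.3-mm voxels — with tube axes tilted 5–8°
off the grid axes. The tilt spreads partial-volume phase along each tube,
so per-section measurement errors average out instead of aliasing with the
lattice; the spread of perimeters conditions the Pi10 regression.

### Subject cohorts

`generate_cohort()` draws covariates first and then COPD from one logistic
model over all seven covariates (demographics + biomarkers). An earlier
design that drew biomarkers *conditionally on* COPD status was discarded:
it does not induce a logistic conditional law with known coefficients, so
"the full-model fit recovers the generating coefficients" — the key
testable property — would have no exact meaning. With the joint-logistic
design the fitted model is correctly specified and recovery within
sampling error is guaranteed.

Marginals are configured to the screening population: age 62.5 ± 5.2 y
(bounded 50–75), BMI 27.1 ± 3.6 (bounded 15–50), 53.4% current smokers,
packyears log-normal with median 38 and IQR 28–49 (the two published
quantiles identify both log-normal parameters in closed form:
`meanlog = log 38`, `sdlog = log(49/28)/(2 z0.75)`), left-truncated at the
16.5-packyear screening entry criterion. The emphysema index is log-normal
(median 0.75%, IQR 0.40–1.46), the air-trapping ratio normal
(0.84 ± 0.059) and Pi10 normal (2.41 ± 0.51 mm). Covariates are generated
independently: no joint distribution (e.g. age × packyears correlation) is
published, so independence is the least-assumption default, and all
parameters are configurable.

The generating intercept is solved numerically on the realized linear
predictor so the expected prevalence equals `target_prevalence` (default
38.3%); passing a finite `intercept` in `true_coefficients` disables this.
The default slopes were chosen once so that the full model's apparent
C-statistic on an n = 1140 cohort falls in 0.82–0.92 (a realistic
discrimination regime for this problem) and then frozen. Spirometry is
drawn *consistently with* the sampled COPD label — FEV1/FVC below 0.70 iff
COPD, FEV1 %predicted within the severity band, severities mixed
63.4/30.9/5.7% — so the spirometric classifier can be cross-checked
against the generator. Symptom prevalence is not published; the default is
0.5 and configurable.

## Airway quantification

`segment_lumen()` grows a 6-connected region of sub-threshold voxels from
a seed in the lumen. The threshold starts conservatively (−950 HU) and is
raised in doubling increments (8, 16, 32, … HU); a step that multiplies
the region volume by more than `leak_factor` (default 3) is a leak into
the parenchyma and is rejected, keeping the last safe threshold. This is a
deliberately simplified, single-threshold stand-in for tree-oriented
multi-threshold region growing; it is not claimed equivalent. If even the
base threshold floods more than a quarter of the grid the mask is returned
with a `failed` flag rather than an error, mirroring how segmentation
failures are tallied (not raised) downstream.

`extract_centerline()` converts the mask to a centerline tree by geodesic
wavefront propagation: 26-connected breadth-first distance from the root
voxel, one node per connected component of each distance shell (at its
centroid), parent links by voxel adjacency across consecutive shells.
Leaf branches shorter than `spur_mm` (default 3 mm) are pruned as skeleton
spurs and the touching branches re-merged. Generations count bifurcations
from the root: 0 = trachea, 1 = main bronchi, ≥ 2 = measurable bronchi.

`measure_wall()` casts 72 equally spaced rays in the plane perpendicular
to the local airway direction, sampling HU by trilinear interpolation at
0.1-mm steps. Boundaries use a full-width-at-half-maximum edge rule: the
inner boundary is the half-rise between the lumen plateau (first 0.4 mm of
the ray plus the center sample) and the wall peak; the outer boundary the
half-fall between the peak and the parenchymal plateau (trailing 15% of
the ray). The published intensity-integration detector is unpublished in
algorithmic detail; FWHM is the standard documented substitute and is
*not* claimed equivalent — it is known to overestimate very thin walls.
A ray with peak-over-plateau contrast under 150 HU is *missing*; a section
with more than 25% missing rays is excluded as a wall-segmentation
failure, otherwise missing radii are interpolated angularly between the
nearest observed neighbours. Per-ray radii are regularized by a 5-ray
circular moving average before polygon construction: lattice quantization
puts zero-mean jitter on the radii, and the perimeter of a raw zigzag
polygon is biased upward by several percent, while a short angular mean
suppresses the jitter without flattening anatomically plausible
(low-angular-frequency) shape. Pi is the perimeter of the inner polygon;
WA the outer-polygon area minus the inner-polygon area (shoelace formula).

`filter_cross_sections()` removes trachea (generation 0), main bronchi
(generation 1), sections within `bifurcation_margin_mm` (default 2 mm — no
published distance exists; configurable) of a bifurcation, and failed
sections, tallying each exclusion reason. `compute_pi10()` then runs the
√WA-on-Pi regression; it requires at least two sections with distinct
perimeters and errors otherwise rather than extrapolating from a
degenerate cluster.

## Statistical machinery

* **Fitting** is maximum-likelihood logistic regression via IRLS
  (`stats::glm.fit`), with covariates standardized internally for
  conditioning and coefficients reported on the original scale
  (covariance back-transformed exactly). Complete separation and
  non-convergence raise typed errors; missing covariates are rejected
  outright — the published analysis used multiple imputation for its few
  missing values, which is deliberately out of scope here, and silent
  row-dropping would bias prevalence.
* **Discrimination** is the concordance C-statistic computed from
  midranks (ties count one half), with a DeLong placement-value variance
  and normal-approximation CI truncated to [0, 1]. Both are cross-checked
  against an all-pairs enumeration and against `pROC` in the test suite.
* **Internal validation** is the bootstrap optimism procedure: refit on
  each resample, optimism = mean(C on resample − C of the resample model
  on the original data), corrected C = apparent − optimism. Resamples with
  a single outcome class are redrawn (at most 10 times, logged). The
  shrinkage factor is the mean bootstrap calibration slope (logistic slope
  of the original outcomes on the resample model's linear predictor),
  clipped to (0, 1]; slopes are multiplied by it and the intercept
  re-estimated by an offset-only refit, so shrinkage never increases any
  slope magnitude. A known limitation, visible in the package's own
  null-simulation test: in the extreme-overfit regime (many uninformative
  predictors, modest n) the optimism estimate is itself optimistic,
  because the resample model retains apparent skill on the ~63% of
  original subjects it was trained on, so the corrected C of a pure-noise
  model sits somewhat above 0.5 on average.
* **Cutoffs** maximize TP + TN over thresholds at midpoints of adjacent
  sorted unique risks plus both classify-all extremes; ties go to the
  lowest threshold (the sensitive side), and subjects at the threshold are
  classified positive.
* **NRI** is computed from per-subject classifications at each model's own
  optimal-accuracy cutoff: event NRI = net FN→TP shifts / events,
  non-event NRI = net FP→TN shifts / non-events, total = sum, in percent.
  `compute_nri_marginal()` provides the aggregate-count variant for
  published confusion tables. Models containing the expiratory
  air-trapping term are additionally compared to the same model without it
  (the inspiratory-only twin), quantifying what the expiratory acquisition
  adds.
* **Calibration** uses equal-frequency bins (sizes differ by at most one);
  constant predictions collapse to a single bin.

## Numerical choices and degenerate inputs

Thresholding is strict (`< −950`), so boundary voxels are excluded by
definition. Empty masks, single-class outcomes, zero-variance regressors
and out-of-volume geometry raise typed conditions (`copdct_*_error`)
naming the problem. Voxel indices are 0-based in world-coordinate
formulas, with voxel centers at `(index + 0.5) * spacing`; all world
coordinates are in millimetres, volumes in litres, HU unscaled.

Problem sizes used by the test-suite and acceptance computations — cohort
moments at n = 5000, coefficient recovery at n = 20000, the ladder at the
study size n = 1140 with B = 500 bootstrap iterations, phantoms of ~10⁶
voxels at 0.3–0.5-mm spacing — were chosen so each check is decisively
powered for its tolerance.

## Known limitations

* The lumen segmentation and wall detector are documented simplifications
  of unpublished proprietary algorithms; absolute agreement with those
  systems is not claimed, only agreement with geometric ground truth.
* Phantom realism is geometric, not radiological (no texture, no scanner
  model); densitometry on clinical data additionally depends on the
  upstream lung segmentation, which is out of scope.
* The optimism correction inherits the null-regime bias described above.
* Severity grading below 30% predicted FEV1 is not defined by the banding
  used here; such subjects are graded severe and flagged
  (`below_grading_range`).
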