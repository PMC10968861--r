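---
title: "Longitudinal PET/CT delta radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal PET/CT delta radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`deltaradiomics` implements a longitudinal ("delta") PET/CT radiomics
pipeline for predicting treatment outcome in lymphoma: feature extraction
from co-registered PET (SUV) and CT (HU) volumes with lesion masks at two
time points (pre-treatment baseline and end of treatment, EoT), computation
of between-time-point feature changes, scanner-effect testing and
harmonization, relapse/progression classification under nested
cross-validation, time-to-progression (TTP) survival analysis, and
recurrence-volume regression. Because clinical PET/CT cohorts of this kind
are private, the package ships a synthetic cohort generator with known
ground truth; every stage is tested against it and against closed-form or
brute-force oracles.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic experiments do and do not establish.

## Single-time-point features

For each scan the package computes, per modality (PET, CT):

* **First order**: maximum and mean intensity, metabolic tumor volume
  (MTV, ml; voxel count times voxel volume), total lesion glycolysis
  (TLG = SUVmean x MTV), and grey-level entropy (base 2) over the
  discretized-intensity histogram.
* **AUC-CSH** (PET only): the area under the cumulative SUV-volume
  histogram, `CSH(t) =` fraction of ROI volume with SUV at least
  `t * SUVmax`, integrated by the trapezoid rule on a 100-point grid.
  Values near 1 indicate homogeneous uptake; lower values more
  heterogeneity. The grid resolution bounds the discretization error of
  the area by `1/(2(n-1))`.
* **Dmax** (PET mask): the largest pairwise Euclidean distance between
  centroids of 26-connected lesion components, in mm; 0 for a single
  lesion. Centroids (rather than extreme voxels) make the quantity robust
  to single-voxel protrusions.
* **GLRLM** grey-level non-uniformity (GLN) and run-length non-uniformity
  (RLN). Runs are enumerated in all 13 unique 3D directions and the
  per-direction run matrices are summed into a single matrix before the
  features are computed; out-of-mask voxels break runs. Merging the
  directions gives one deterministic matrix; the brute-force test oracle
  follows the same convention.
* **NGTDM** busyness, coarseness, complexity, contrast and strength
  (Amadasun-style definitions over the 26-neighbourhood). Degenerate
  denominators are guarded with documented sentinels: coarseness returns
  `1e6` and strength 0 when the ROI is homogeneous (`sum s_i = 0`),
  busyness 0 when its denominator vanishes, contrast 0 with a single
  occupied grey level. The guards keep feature tables finite on flat or
  single-voxel ROIs.

Intensities are discretized with fixed bin widths: 0.3125 SUV into 64 grey
levels for PET and 10 HU into 400 levels for CT. The bin anchor is a
genuinely open choice; the default anchors bins at the ROI minimum
(`anchor = "roi_min"`, the common radiomics-library behaviour), with an
absolute-zero anchor available by configuration, and levels are clipped to
the configured count either way.

CT features reuse the PET-derived mask: the volumes are assumed
co-registered (hybrid-scanner acquisition), and no re-segmentation is done
on CT.

## Radial shell (RIM) features

The ROI is peeled one voxel layer at a time: with `M_0` the mask and
`M_(k+1) = erode(M_k)`, shell `k` is `M_k \ M_(k+1)`. Erosion uses the
6-connected (face-adjacency) structuring element so each layer has a
thickness of one voxel face-to-face; 26-connectivity is available by
argument. Shells are disjoint and exactly partition the mask — this is
asserted as a property test. Per shell the package records min, mean, SD
and max intensity, voxel count, approximate volume and intensity sum.

Lesions differ in depth, so shell profiles have ragged length. The flat
feature vector indexes shells twice: `RIM_<stat>_<k>` from the outermost
envelope inward and `RIMcore_<stat>_<k>` from the innermost shell outward.
The core-based names make "innermost shell" analyses stable across lesions
of different depth. Profiles shorter than `K_fixed` (default 6; 4 in the
bundled experiments, matching the lesion radii the generator produces) are
padded with missing values and mean-imputed downstream; longer profiles
are truncated. A sphere-shell (concentric ball) partition is deliberately
not provided: on irregular lesions such shells mix intra- and peritumoral
voxels, which is the reason the erosion-envelope construction is used.

## Delta features and harmonization

Two delta definitions are computed per feature: the absolute change
`EoT - baseline` and the relative change `(EoT - baseline)/baseline`.
Relative deltas with near-zero baseline (below `1e-8` of the column
median magnitude) become missing values and are mean-imputed later;
clipping was rejected because it fabricates large but arbitrary ratios.
The identity `delta_rel = delta_abs / baseline` holds exactly wherever
the guard does not fire, and is tested exactly. Seven feature-set
combinations are supported: baseline, EoT, baseline+EoT, relative delta,
absolute delta, baseline+relative, baseline+absolute.

Scanner effects are probed per feature with a Welch two-sample t-test
(additive, mean shift) and Bartlett's test (multiplicative,
heteroscedasticity). Welch rather than pooled-variance: heteroscedasticity
is precisely what the companion test probes, so equal variances are not
assumed. Raw-p flags at `alpha` and Benjamini-Hochberg-adjusted flags are
both reported; no correction is silently imposed.

Harmonization uses a longitudinal ComBat-style adjustment written for the
two-scans-per-subject design: per feature, a linear model with subject
intercepts, a time-point effect and a scanner term estimates the batch
location from within-subject contrasts (subjects scanned on different
machines at the two time points are what identify it — with scanner
perfectly nested in subject the model falls back to between-subject means
with a warning); batch scale comes from per-batch residual variances
around the time-point fit, so between-subject variability remains visible
to the scale estimate. Batch locations and scales are shrunk across
features by parametric empirical Bayes (normal prior on locations,
inverse-gamma on scales, the classic ComBat iteration), and the adjusted
table is the non-batch fit plus standardized residuals with batch effects
removed. Location-plus-scale adjustment with shrinkage is the default;
`adjust = "location"` with `eb = FALSE` removes the raw batch shifts
exactly and is exactly idempotent (the default is idempotent only up to
shrinkage noise, which is why the exact invariant is stated for that
mode). A Kolmogorov-Smirnov per-feature comparison of before/after tables
is the standard post-check; harmonization is provided as an explicit step,
not auto-applied when tests fire, since a study may legitimately conclude
after testing that no adjustment is needed.

## ICARE: binary-weighted ensemble risk model

A single ICARE member model is deliberately minimal, to resist overfitting
on small cohorts: features are z-scored on the training sample; each
feature's univariate performance `u_j` is its AUC against the binary label
(classification) or the Harrell concordance of the feature used directly
as a risk score (survival); the feature's weight is the sign
`w_j = +1 if u_j > 0.5 else -1` and its margin is `|u_j - 0.5|`. Features
with margin below `Cmin` are dropped; survivors are greedily decorrelated
(visited by descending margin, dropping any feature correlated above `rho`
with a kept one); at most `F` of the survivors are kept, drawn at random
(filter first, subsample second — the subsample is the ensemble's
diversity mechanism, so it acts on the already-validated pool). The risk
score is the mean of the sign-weighted z-scored features. Choosing AUC and
Harrell c as the two margins keeps classification and survival symmetric:
both are concordance probabilities on the 0.5-centred scale that `Cmin`
expects.

The bagged ensemble fits `n_models` (default 1000) members on independent
bootstrap resamples and aggregates predictions with the per-sample median.
Randomized tuning samples candidate sets (`F` uniform on `1..min(30, p)`,
`Cmin` on `[0, 0.2]`, `rho` on `[0.3, 1]` — ranges that bracket the
degenerate extremes), scores each by Monte Carlo CV, keeps the top `B`
(itself selected from a small grid by an extra CV loop), and lets each
final member draw one of the top-B sets. All member seeds derive from one
master seed by counter, so the full ensemble is reproducible.

Exact invariances — scale invariance (z-scoring absorbs positive feature
rescaling) and sign equivariance (negating a feature flips its weight and
leaves predictions unchanged) — are asserted to 1e-12, and single-model
fits are checked against an independently coded direct implementation.

## Classification pipeline

The nested-CV protocol: optional stratified holdout (default 15%);
repeated stratified outer folds (defaults 10 folds x 5 repeats); within
each outer-training set, in order: constant-feature removal and greedy
correlation filtering at |r| > 0.8, SMOTE balancing, z-scoring, and
sequential forward selection (SFS) scored by inner CV (defaults 5 folds x
20 repeats, F1 metric, ties to the lowest column index); then the final
model fit. Metrics (accuracy, F1, recall, precision, ROC AUC) are computed
on the outer-test folds and aggregated as mean and SD over all outer-fold
x repeat evaluations (the SD convention is reported explicitly since
"SD over folds" and "SD over repeats" differ).

SMOTE placement is a documented fork: `within_fold` (default) balances
each outer-training set only, so no synthetic sample ever derives from a
test row; `before_split` balances the whole dataset first — the literal
"after balancing the dataset" ordering — and is provided for comparison
because it leaks information and inflates metrics. The leak-freeness of
the default is tested with a canary feature equal to the label on exactly
the held-out rows: it cannot lift held-out accuracy.

Classifiers: KNN (k tunable, default 5), LDA (with a diagonal
nearest-centroid fallback when the within-class covariance is singular,
e.g. a perfectly separating feature), random forest (500 trees by
default), and the ICARE ensemble (decision threshold 0 on its centred risk
score; 0.5 for the probability models). Greedy SFS cannot assemble jointly
predictive but marginally useless pairs; this is asserted on a constructed
XOR instance rather than hidden.

## Survival and regression

Harrell's c-index uses the standard comparable-pair rule: pairs
`(i, j)` with `time_i < time_j` and an event at `i`; concordant when
`risk_i > risk_j` (higher risk, shorter time — the anti-concordant risk
orientation of the ICARE survival models); tied risks count 0.5;
censored-before-event pairs are incomparable; tied event times enter only
through the strict `<`. The implementation is verified against exhaustive
pair enumeration and against `survival::concordance`.

The CoxNet model standardizes features, fits the elastic-net Cox path
(`glmnet`) for each mixing value on a grid (default 0.5/0.9/1.0, path of
50 penalties down to ratio 0.01), and selects the (mixing, penalty) pair
by shuffled 10-fold CV maximizing the mean Harrell c. Five
feature-selection front-ends (SFS, chi-square on nonnegative-shifted
features, quantile-binned mutual information, random-forest Gini
importance, lasso entry order) select against the *binary* progression
label before the survival fit — a deliberate design choice (selection stays task-agnostic and cheap) even though
selecting on the survival outcome directly would be statistically
preferable; both the faithful default and time-aware use are possible
since selection and fit are separate calls.

Recurrence-volume regression standardizes features and target, removes
correlated features, grid-searches a gradient-boosting regressor
(number of trees, learning rate, depth, minimum child weight) by CV, and
reports cross-validated R2, MAE and MAPE on the standardized scale
(raw-scale MAE as well). Standardized targets with magnitude below 0.01
are excluded from MAPE, with the excluded count reported.

## The synthetic cohort: what it emulates, and what it does not

Default study conditions: 31 subjects (a realistic size for a
single-center two-time-point lymphoma cohort), 4 mm isotropic grids, one bulky lesion per subject
with radius 14-30 mm, peak SUV 6-20 above a background of 1 with a radial
uptake gradient `peak * (1 - (r/R)^g)` (g = 2), Gaussian PET noise
(SD 0.15 SUV) and CT soft tissue at 40 HU with a +25 HU lesion offset.
"Treatment" multiplies lesion volume by a shrinkage factor — uniform on
[0.05, 0.35] for responders (80% of subjects) and [0.6, 1.1] for
non-responders — and rescales the gradient exponent (heterogeneity
change). The latent response score is the true (noise-free) relative TLG
change plus 0.5 times the relative change in the gradient exponent;
progression is Bernoulli with a logistic link (intercept 0.7, slope 4,
giving a marginal progression rate near 16%, typical of such cohorts); TTP is Weibull (shape 1.5, scale 60 months, hazard proportional
to `exp(2 * score)`), with censoring applied with probability 0.3 as a
uniform draw before the event time (months scale, with multi-year
follow-up typical of lymphoma cohorts). Two scanners are assigned per scan with equal probability; the
additive shift and noise-inflation knobs default to zero effect and are
switched on only in harmonization tests. Lesions are spheres with an
optional low-frequency radial modulation; spheres give analytic oracles
for MTV and the shell profiles while the modulation exercises the
irregular-shape code paths.

The bundled experiments use 100-subject cohorts on 28-voxel grids at 5 mm
spacing with lesion radii 15-28 mm and 4 shell positions — sizes chosen so
a full replicate (simulation, 200 extractions, three nested-CV runs)
completes in well under a minute while keeping ROIs large enough for
texture and shell structure.

Deliberate limitations: the generator does not model scanner point-spread
or reconstruction, respiratory motion, multi-organ anatomy, or multiple
lesions interacting with registration. The response process is independent
of the baseline lesion (shrinkage is drawn per subject regardless of size
or uptake), with two consequences worth knowing: baseline-only feature
sets are nearly uninformative for progression — which is what makes the
delta-beats-baseline comparison a clean recovery test — and the
end-of-treatment volume is only weakly predictable from baseline features,
so the recurrence-regression experiment reports a near-zero cross-validated
R2 on synthetic data. The regression module's correctness is instead
established by a noiseless-recovery test (R2 > 0.95-level recovery when
the target is an exact function of two features) and a null-target test.
Passing the synthetic suite therefore shows the machinery is correct and
leak-free under known ground truth; it does not certify effect sizes on
clinical data.

## Numerical and reproducibility choices

* All randomness flows from a single integer seed; per-stage streams are
  derived from it with a label hash, so stages are independently
  reproducible and the full CLI chain is byte-identical across runs with
  the same seed (asserted in the test suite).
* Missing values serialize as empty CSV fields, never sentinel numbers;
  tables round-trip losslessly at double precision (15 significant
  digits).
* Z-scoring uses the population SD and maps zero-variance columns to 0;
  statistics fitted on a training partition are reused verbatim on
  held-out data.
* A nested-CV fold whose training part cannot be SMOTE-balanced
  (minority below 2) proceeds unbalanced with a warning rather than
  failing the whole run; stratification makes this rare.
* Erosion at a 1-voxel-thick structure empties the mask (a plane yields a
  single shell), and a single-voxel ROI yields defined first-order
  features with guarded texture values.
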