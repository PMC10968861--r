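# deltaradiomics

Longitudinal ("delta") PET/CT radiomics for lymphoma outcome prediction.

## The problem

After chemotherapy for aggressive lymphoma, clinicians must judge from the
end-of-treatment (EoT) [18F]FDG PET/CT scan which patients are likely to
relapse or progress. Single-time-point radiomic signatures ignore how the
tumor *changed* under treatment. Delta radiomics quantifies that change:
for each radiomic feature f,

```
Δf_absolute = f(EoT) − f(baseline)
Δf_relative = (f(EoT) − f(baseline)) / f(baseline)
```

and uses the deltas — alone or combined with the baseline values — to
predict relapse/progression (classification) and time to progression
(TTP, survival analysis).

`deltaradiomics` is a tested, reusable implementation of that pipeline for
researchers working with paired baseline/EoT PET/CT scans and lesion
masks. It provides:

* **Feature extraction** per scan and modality: SUVmax, SUVmean, MTV, TLG,
  grey-level entropy, tumor dissemination (Dmax), the area under the
  cumulative SUV-volume histogram (AUC-CSH), NGTDM texture features
  (busyness, coarseness, complexity, contrast, strength) and GLRLM
  non-uniformities (GLN, RLN), with fixed-bin discretization (0.3125 SUV /
  64 levels for PET, 10 HU / 400 levels for CT).
* **Radial intensity mean (RIM) shell features**: the ROI is peeled one
  voxel layer at a time by iterated 3D erosion, from the outer envelope to
  the core, recording per-shell intensity statistics — indexed both from
  the surface and from the core.
* **Longitudinal processing**: absolute/relative deltas, the seven
  feature-set combinations (baseline, EoT, baseline+EoT, deltas,
  baseline+deltas), mean imputation, z-scoring, Welch-t / Bartlett
  scanner-effect tests, a longitudinal ComBat-style harmonization with
  empirical-Bayes shrinkage and a Kolmogorov–Smirnov post-check.
* **ICARE**: the binary-weighted (±1) minimal-learning risk model and its
  bagged, randomized-hyperparameter ensemble (F features per member, a
  univariate-margin filter Cmin, a decorrelation threshold ρ, median
  aggregation), for both classification and survival.
* **A nested cross-validation harness** (stratified outer/inner folds with
  repeats, correlation filtering, SMOTE balancing, sequential forward
  selection, KNN/LDA/RF/ICARE) with leak-free defaults — every
  data-dependent statistic is fitted on outer-training data only.
* **Survival and regression**: Harrell's c-index, elastic-net Cox (CoxNet)
  over a cross-validated penalty path with five feature-selection
  front-ends (SFS, chi-square, mutual information, RF importance, lasso),
  and gradient-boosted regression of recurrence (EoT) tumor volume from
  baseline features.
* **A synthetic two-time-point cohort generator** with known ground truth
  (lesion geometry, latent response score, progression probabilities, TTP
  model, scanner effects), so the entire pipeline is testable without
  patient data.

## Worked example

Simulate a 40-subject cohort, extract features at both time points, build
relative-delta features and estimate nested-CV performance:

```r
library(deltaradiomics)

spec <- cohort_spec(n_subjects = 40, grid_shape = c(24L, 24L, 24L),
                    spacing = c(5, 5, 5), radius_range_mm = c(14, 24),
                    beta0 = 1.2, seed = 42)
cohort <- simulate_cohort(spec)
cohort$scans[[1]]$baseline
#> <scan_pair> S001 / baseline | grid 24x24x24 | spacing 5x5x5 mm | ROI 136 voxels | scanner D690

baseline <- extract_feature_table(lapply(cohort$scans, `[[`, "baseline"), rim_k = 4)
eot      <- extract_feature_table(lapply(cohort$scans, `[[`, "eot"),      rim_k = 4)
baseline[1:3, c("subject_id", "PET_SUVmax", "PET_MTV_ml", "PET_TLG", "PET_AUC_CSH")]
#>   subject_id PET_SUVmax PET_MTV_ml PET_TLG PET_AUC_CSH
#> 1       S001      7.747         17   62.23      0.4730
#> 2       S002      9.929         17   74.75      0.4426
#> 3       S003     11.624         26  131.16      0.4344

fs <- mean_impute(build_feature_set(list(baseline = baseline, eot = eot),
                                    "rel_delta"))
X <- as.matrix(fs[, feature_columns(fs)])
report <- nested_cv_classify(
  X, cohort$outcomes$progression, model = "lda",
  cfg = cv_config(outer_folds = 5L, outer_repeats = 2L, inner_folds = 3L,
                  inner_repeats = 1L, holdout_fraction = 0,
                  max_features = 3L, seed = 42))
report
#> <cv_report> lda - mean +/- SD over 10 outer evaluations
#>   accuracy  0.838 +/- 0.156
#>   f1        0.737 +/- 0.236
#>   recall    0.700 +/- 0.350
#>   precision 0.769 +/- 0.294
#>   roc_auc   0.842 +/- 0.224
```

Subject S001's baseline lesion has 136 mask voxels at 5 mm spacing, hence
MTV = 136 × 0.125 ml = 17 ml; TLG is SUVmean × MTV; AUC-CSH ≈ 0.47
reflects the radial uptake gradient (heterogeneous uptake). Relative-delta
features classify progression at ~0.84 accuracy here because, in the
generator, progression is driven by the relative TLG change plus a
heterogeneity-change term; baseline-only features, by design uninformative
about response, stay near chance.

On real data, replace the simulation with `read_scan_pair()` (NIfTI
volumes + mask per time point) and an outcomes CSV (`subject_id`,
`progression`, `ttp_months`, `event`, `scanner_id`).

A command-line wrapper over the same functions is installed at
`inst/cli/deltaradiomics.R` with one verb per stage
(`simulate | extract | delta | harmonize | classify | ttp | recurrence`),
each reading a single YAML config; chains driven by one seed are
byte-reproducible.

See `vignettes/delta-radiomics-methods.Rmd` for the models, parameter
choices, numerical conventions and known limitations.

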