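Package: deltaradiomics
Title: Longitudinal (Delta) PET/CT Radiomics for Lymphoma Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for longitudinal ("delta") PET/CT radiomics
    analysis of treatment response in lymphoma. Extracts conventional,
    texture (GLRLM, NGTDM) and radial shell (erosion-envelope) features from
    co-registered PET/CT volumes with lesion masks, computes absolute and
    relative between-time-point feature changes, tests and harmonizes
    scanner effects (longitudinal ComBat variant), predicts
    relapse/progression with a binary-weighted ensemble risk model (ICARE)
    and standard classifiers under nested cross-validation with SMOTE and
    sequential feature selection, performs elastic-net Cox time-to-progression
    analysis with Harrell concordance, and regresses recurrence tumor volume
    with gradient boosting. Includes a synthetic two-time-point PET/CT cohort
    generator with known ground truth so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    MASS,
    randomForest,
    caret,
    glmnet,
    survival,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
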