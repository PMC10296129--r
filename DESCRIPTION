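Package: proprioscore
Title: Normative Scoring and Outcome Prediction for Robotic Arm Position
    Matching After Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying proprioceptive performance on the robotic
    arm position matching task and predicting persistent impairment after
    stroke. Computes the eight trial-level matching parameters (absolute
    error, variability, contraction/expansion and shift, each per axis),
    converts them into demographically adjusted z-scores via Box-Cox
    normalisation and weighted covariate regression against a control
    population, and summarises them as a non-negative composite Task Score
    with a 1.96 impairment threshold. Derives lesion volume and a
    voxel-based lesion-symptom mapping (VLSM) mean-Z feature from binary
    lesion masks, runs the univariate association battery, and evaluates
    five logistic-regression classifier configurations with stratified
    k-fold cross-validation. A synthetic-cohort generator provides control
    populations and stroke cohorts with the statistical structure the
    analysis assumes, so the full pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Matrix,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
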