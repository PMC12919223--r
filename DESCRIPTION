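Package: adscreen
Title: Zero-Burden ADRD Risk Screening from Claims-Style Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating a passive screening score for
    Alzheimer's disease and related dementias (ADRD) from routine electronic
    health record code streams. Implements hierarchical prefix expansion of
    diagnosis, therapeutic-prescription and procedure codes; case/control
    cohort construction with index dates, observation windows and prediction
    horizons; binary presence and cubed odds-ratio feature embeddings; a
    stacked gradient-boosted ensemble risk score; prevalence-standardized
    screening metrics (PPV, NPV, likelihood ratios) at a target specificity;
    and a misclassification-corrected, ridge-regularized odds-ratio estimator
    (the lambda-OR) with delta-method inference for effect-size attribution
    under noisy case/control labels. A synthetic cohort generator with planted
    per-code effects and known label-noise rates supports end-to-end testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xgboost,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
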