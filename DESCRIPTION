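Package: cheradiomics
Title: Radiomics Classification Pipeline for Covert Hepatic Encephalopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for precuneus-based radiomic classification of
    covert hepatic encephalopathy (CHE) in cirrhotic patients. Extracts a
    423-feature radiomic space per region of interest (14 histogram intensity
    features, 22 gray-level co-occurrence matrix features, 11 gray-level
    run-length matrix features, and the same 47 on each of 8 stationary Haar
    wavelet subbands) from masked 3D brain volumes; runs a three-stage feature
    selection cascade (normality-gated univariate testing, Spearman redundancy
    pruning, LASSO with 10-fold cross-validation); fits radiomics-only and
    radiomics-plus-clinical logistic classifiers with ROC/DeLong evaluation;
    and produces nomogram, calibration (Hosmer-Lemeshow) and Spearman
    correlation outputs. Ships a synthetic-cohort generator (Gaussian random
    field volumes plus clinical covariates) so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
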