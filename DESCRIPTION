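Package: pertpred
Title: Predicting Gene Responses to Transcription Factor Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts which genes respond to the perturbation of a
    transcription factor (TF) using only features measured in unperturbed
    cells: TF binding signal binned over cis-regulatory regions, histone-mark
    and chromatin-accessibility coverage, promoter dinucleotide frequencies,
    and preperturbation expression level and expression variation (LOESS
    residual of the coefficient of variation). Models are gradient-boosted
    tree classifiers trained with TF-grouped cross-validation so every
    prediction is made for a TF unseen during training. Includes
    precision-recall evaluation against per-TF random expectation, a
    permutation null with a log-standard-deviation linear model for per-TF
    significance, SHAP-value aggregation for model explanation, and a
    synthetic-data generator with planted effect structure for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    xgboost,
    jsonlite,
    yaml,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
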