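Package: methylRate
Title: Cross-Tissue Comparison of DNA Methylation Ageing Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the rate of age-associated DNA methylation
    change between tissues measured on the same subjects. Implements
    paired-tissue age epigenome-wide association studies with covariate
    adjustment and Bonferroni control, selection of CpGs age-associated in
    both tissues, elastic-net epigenetic clock construction with
    leave-one-dataset-out and k-fold cross-validation, cross-tissue clock
    application, and slope-based ageing-rate inference. Includes a synthetic
    paired-tissue cohort generator with ground truth for calibration and
    parameter-recovery testing, plus intensity-to-beta conversion, sex and
    density quality control, probe filtering, and fixed-reference quantile
    normalization surrogates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
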