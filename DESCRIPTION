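Package: thyromics
Title: Longitudinal Plasma-Omics Screening for Thyroid-Hormone Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal plasma metabolome and proteome
    studies of experimentally induced thyrotoxicosis. Provides a synthetic-data
    generator emulating a 16-subject, five-time-point levothyroxine challenge;
    run-day median normalization, missingness filtering and log10 transformation;
    per-feature linear mixed-effect screening of free-thyroxine (FT4)
    associations with Benjamini-Hochberg false discovery rate control; a
    leave-three-out subsampling scheme that averages estimates and FDR values
    across 101 participant subsets; baseline-relative mean log2 fold-change
    summaries; and a two-stage nested cross-validation random-forest procedure
    that selects a fixed-size biomarker panel with AUC-weighted Gini importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
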