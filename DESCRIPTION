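Package: t2drisk
Title: Diagnosis and Prognosis Risk Modelling for Type 2 Diabetes from
    Heterogeneous Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully seeded analysis pipeline for building
    gradient-boosted-tree diagnosis and prognosis models of type 2 diabetes
    from heterogeneous tabular cohort data. Provides a synthetic cohort
    generator emulating a population study with block-structured
    missingness and municipality links; geospatial augmentation via
    recency-weighted moving averages of pollution series and
    inverse-distance-weighted spatial imputation; semantic feature
    engineering for questionnaire data; per-feature imputer selection by a
    completeness-weighted quality score with a distribution-discernibility
    gate; quasi-constancy filtering via a Gini-based index; repeated-split
    permutation importance with confidence-interval gating and backward
    sequential feature selection; hyperparameter tuning by a tree-structured
    Parzen estimator; region-grouped cross-validated evaluation with
    Youden-index threshold metrics; and partial-dependence explainability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    ranger,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
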