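Package: mhpheno
Title: Mental-Health Phenotyping of Patient-Reported Outcomes in People with HIV
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover and characterize mental-health phenotypes from
    self-report questionnaires (PHQ-9, BAI, PCL-C, CTQ) in cohorts of people
    with HIV. Implements instrument scoring with clinical severity bands,
    nonlinear dimension reduction (UMAP) followed by hierarchical density-based
    clustering (HDBSCAN) of total symptom scores, item-level cluster profiles,
    referent-cluster univariate inference (Welch t and Pearson chi-square),
    and a gradient-boosted classifier with maximal-information-coefficient
    redundancy pruning, optional two-way interaction features, saturation-based
    forward feature selection, and repeated cross-validated F1. A seeded
    synthetic-cohort generator calibrated to published per-cluster summary
    statistics exercises the full pipeline without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
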