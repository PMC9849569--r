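Package: symptomnet
Title: Longitudinal Symptom Network Analysis for Ordinal Questionnaire Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Regularized partial-correlation (Gaussian graphical model)
    network analysis for multi-wave ordinal questionnaire data such as
    PHQ-9/GAD-7 panels: graphical-lasso estimation with EBIC penalty
    selection, strength and bridge centrality over a two-community symptom
    partition, bootstrap edge accuracy and case-dropping centrality
    stability (CS coefficients), a paired permutation Network Comparison
    Test across waves, per-participant OLS-slope change-trajectory
    networks, simulation-based sample-size planning, and a synthetic
    cohort generator with known network structure, wave drift and
    age-dependent dropout for validating every stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
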