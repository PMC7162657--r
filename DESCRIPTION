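Package: ctrlenergy
Title: Control Energy of Structural Brain Network State Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models how structural brain networks energetically support
    transitions to a fronto-parietal activation state using linear network
    control theory. Provides the multi-point optimal control solver (costate
    shooting via the augmented-system matrix exponential), adjacency
    normalization variants and graph metrics, degree- and strength-preserving
    null networks, penalized-spline developmental models with FDR correction
    and partial-correlation effect sizes, nested cross-validated ridge
    prediction of brain maturity with Haufe-transformed weights, bootstrapped
    mediation, and a seeded synthetic-cohort generator so the full pipeline
    can be exercised end-to-end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    data.table,
    igraph,
    mgcv,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
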