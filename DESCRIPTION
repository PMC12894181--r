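Package: cctforest
Title: Instrumental Causal Forests for Randomised Trials with Non-Compliance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of local average and conditional local average
    treatment effects (LATE/CLATE) in randomised encouragement designs with
    non-compliance, such as conditional cash transfer experiments. Implements
    honest, subsampled tree ensembles with out-of-bag prediction; instrumental
    causal forests grown on residualised data with local two-stage least
    squares leaf estimates; doubly robust (AIPW) scores and compliance scores;
    heterogeneity summaries (best linear predictors, classification analysis,
    variable importance); exhaustive depth-limited policy-tree learning; and a
    synthetic trial generator with known principal strata and ground-truth
    effect functions for validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    sandwich,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
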