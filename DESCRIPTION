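Package: chacomed
Title: Structural Disconnection Scoring and Causal Mediation for Stroke
    Thrombolysis Trials
Version: 0.1.0
Authors@R:
    person("chacomed", "authors", email = "chacomed@example.org", role = c("aut", "cre"))
Description: Tools for analysing the effect of thrombolysis on structural
    brain connectivity and functional outcome in randomized stroke trials.
    Computes Change-of-Connectivity (ChaCo) disconnection profiles by
    embedding binary lesion masks in reference whole-brain tractograms,
    models disconnection progression with two-part mixed models, ranks
    candidate mediator regions by treatment responsiveness and clinical
    eloquence, and estimates natural direct and indirect effects for
    multiple-mediator counterfactual mediation via inverse-probability
    weighting with bias-corrected bootstrap inference, step-down false
    discovery rate control, and random-subset null calibration. Includes a
    fully specified synthetic cohort generator with a Monte-Carlo oracle
    for the true natural effects, plus minimal NIfTI-1 and TCK readers and
    writers for the real-data path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    rlang,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
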