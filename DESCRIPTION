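Package: designbias
Title: Quantifying Study-Design Bias in Before-After Control-Impact
    Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the choice of study design biases
    estimates of the effect of an environmental impact or intervention.
    Classifies study designs (After, BA, CI, BACI and their randomised
    counterparts), mimics alternative designs inside
    before-after-control-impact monitoring datasets, estimates log
    response ratios with design-appropriate generalised linear (mixed)
    models, compares estimates across designs, fits a hierarchical
    Bayesian model that partitions estimation error into true-effect
    variation, per-design bias and scaled sampling noise, and pools
    heterogeneous study estimates with a bias-adjusted meta-analysis.
    Includes a synthetic monitoring-data generator with known true
    effects for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
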