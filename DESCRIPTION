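Package: doseslab
Title: Model-Based Dose-Escalation Designs with Subgroup-Aware Spike-and-Slab
    Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian model-based phase-I dose-escalation designs for trials with
    a suspected subgroup effect. Implements the standard two-parameter logistic
    dose-toxicity design with a pseudo-data prior, its four-parameter extension
    with covariates for subgroup membership, and a design that continually
    assesses the presence of a subgroup effect through Dirac-spike/normal-slab
    priors on the subgroup terms, sampled by Polya-Gamma-augmented Gibbs MCMC.
    Includes a full trial simulator (cohort allocation, safety, maximum-size and
    accuracy stopping rules, final dose recommendation) and an
    operating-characteristics study harness with scenario truths reconstructed
    from published trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'doseGrid.R'
    'toxicityData.R'
    'fitModel.R'
    'pseudoPrior.R'
    'spikeSlab.R'
    'trialEngine.R'
    'scenarios.R'
    'simStudy.R'
    'report.R'
    'doseslab-package.R'
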