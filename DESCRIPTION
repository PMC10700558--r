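Package: toebayes
Title: Bayesian Observer Models of the Tactile Time-Order Effect
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative Bayesian observer models for two-alternative
    forced-choice (2AFC) tactile frequency discrimination. A dynamic
    observer carries a Gaussian belief about the stimulus feature across
    stimuli under a "prior of sameness", producing a contraction bias and
    an emergent time-order effect; a static control observer decides on
    the veridical frequency contrast. The package simulates the block
    designs of a detection-threshold experiment and two discrimination
    experiments, fits subjects by maximum a posteriori estimation with
    Laplace model evidence in a two-phase multisession protocol, performs
    random-effects group Bayesian model selection (exceedance and
    protected exceedance probabilities, Bayes omnibus risk) and Bayesian
    model averaging, and computes the behavioral statistics of the tasks:
    time-order-effect index, performance-bias intercept, psychometric
    thresholds, d-prime, exclusion rules, and method-of-limits adaptation
    metrics. Parameter-recovery and model-confusion studies are built in.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
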