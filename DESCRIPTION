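Package: flexrl
Title: Reinforcement-Learning Models of Cognitive Flexibility in Probabilistic Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of probabilistic reversal-learning
    behavior. Provides a generative task engine (80/20 reward contingencies with
    covert reversals after a randomly drawn run of correct choices), three
    reinforcement-learning models of increasing complexity (Rescorla-Wagner,
    risk-sensitive with separate learning rates for positive and negative reward
    prediction errors, and risk-sensitive with anticorrelated valuation of the
    unchosen option), maximum-likelihood fitting of the switch/stay choice
    likelihood with per-trial AIC, random-effects Bayesian model selection for
    groups (Dirichlet posterior and exceedance probabilities), synthetic cohort
    generation for parameter-recovery and model-identification studies, group
    statistics on fitted parameters, and tertile binning of reward prediction
    errors with export of event/regressor tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
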