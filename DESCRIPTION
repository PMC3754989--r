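Package: gainloss
Title: Gain-Loss Reinforcement Learning Models for Probabilistic Reward and
    Punishment Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation, model fitting and scoring for a probabilistic
    category-learning task that interleaves reward-based and punishment-based
    trials. Implements the four-parameter gain-loss reinforcement-learning
    model (separate learning rates for better- and worse-than-expected
    outcomes, a softmax inverse-gain parameter, and a free reinforcement value
    for the ambiguous no-feedback outcome), per-participant maximum-likelihood
    estimation by exhaustive grid search, a parameter-recovery harness,
    behavioral scoring (percent-optimal responding, solver classification by
    exact binomial criterion), synthetic cohort generation, and the
    contingency-table and summary statistics used to analyze group
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
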