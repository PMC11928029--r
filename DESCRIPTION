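Package: aifbandit
Title: Active Inference Modelling of a Contextual Two-Armed Bandit Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a contextual two-armed bandit task with a purchasable
    context cue, and models choice behaviour in it with a discrete-state
    active inference agent whose expected free energy separates into the
    value of reducing novelty, the value of reducing variability, and
    extrinsic value. Provides model-free and model-based reinforcement
    learning baselines, per-participant maximum-likelihood fitting with
    global optimisation and BIC model comparison, synthetic cohort and
    neural-epoch generators, and extraction of trial-wise model regressors
    for mass-univariate regression with false discovery rate correction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
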