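Package: critlearn
Title: Trial-by-Trial Criterion Learning in Signal Detection Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-detection-theoretic models of adaptive decision criterion
    setting in two-choice perceptual tasks. Implements leaky reward-integration
    update rules (integrate rewards, integrate reward omissions, and their
    combination) together with stimulus-specific learning rates and a
    relative-difference variant that restricts the leak to rewarded trials,
    their analytic steady-state equilibria and reward-maximizing criteria, a
    synthetic experiment generator for standard stimulus/reward manipulations,
    maximum-likelihood fitting via probit regression on discounted
    outcome-history regressors with BIC model comparison, forward-simulation
    ensembles, and session-level analyses (one-criterion-per-session
    estimation, outcome-history logistic regression, steady-state summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
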