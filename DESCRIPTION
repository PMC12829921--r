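Package: frailtynet
Title: Neural-Network Frailty Cox Models for Clustered Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Cox proportional-hazards models for clustered
    (within-cluster correlated) right-censored survival outcomes in which
    the linear predictor is replaced by the output of a feed-forward
    neural network and a per-cluster random intercept (frailty) enters as
    a trainable weight in the final layer.  Training minimises a penalized
    approximated partial log-likelihood with mini-batch Adam; the frailty
    variance is refreshed by a moment-type update and the baseline
    cumulative hazard is recovered with a Breslow-type estimator.  Also
    provides the classical comparison fits (linear Cox, Cox with two-way
    interactions, Gaussian-frailty Cox, Cox with fixed cluster effects,
    and a no-frailty deep survival model), a clustered-survival simulation
    engine with two covariate scenarios, within-cluster train/test
    splitting, Harrell's concordance index, the IPCW time-dependent Brier
    score, and a replicated benchmark runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
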