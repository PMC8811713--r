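Package: rlddm
Title: Hierarchical Bayesian Estimation of the Reinforcement Learning
    Drift Diffusion Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting reinforcement learning drift diffusion models
    (RLDDM) to trial-level choice and response-time data from two-alternative
    instrumental learning tasks. Delta-rule value learning feeds trial-wise
    drift rates into a Wiener first-passage-time choice/RT likelihood
    (Navarro-Fuss series approximation, including the 'full' DDM between-trial
    variability parameters). Group and subject parameters are estimated by
    hierarchical Bayesian MCMC (univariate slice sampling), with support for
    condition splits, trial-wise covariate regression onto decision parameters
    (including a latent conflict term), a softmax-only variant for data without
    response times, posterior summaries and convergence diagnostics
    (Gelman-Rubin, autocorrelation, DIC), posterior predictive checks
    (binned choice evolution, signed-RT densities, quantile-probability
    plots), a forward simulator for probabilistic-selection-task datasets, and
    a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    ggplot2,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
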