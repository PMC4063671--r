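Package: priorcue
Title: Factorial Bayesian Observer Models for Probabilistic Target Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a probabilistic target-estimation
    task in which an observer combines an explicitly displayed trial-wise
    prior distribution (an array of discretized target dots) with a noisy
    cue. Provides exact one-dimensional Gaussian-mixture machinery for
    posteriors, expected losses and decision rules; a factorial family of
    suboptimal Bayesian observer models (Bayesian decision theory,
    stochastic-posterior, posterior probability matching and
    sample-averaging decision rules, Gaussian approximations of the
    posterior, cue-estimation noise, noisy prior estimation, lapses);
    slice-sampling MCMC fits with deviance information criterion scores;
    random-effects Bayesian model selection with exceedance probabilities;
    synthetic-cohort generation for parameter and model recovery; and
    nonparametric reconstruction of priors from responses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
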