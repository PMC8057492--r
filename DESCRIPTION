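Package: latentprev
Title: Bayesian Latent-Class Prevalence Estimation from Two Imperfect
    Diagnostic Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the population prevalence of a condition from two
    imperfect binary measures (for example a survey structured-interview
    diagnosis and a health-administrative diagnosis) observed on the same
    sample, using a two-test latent-class model without a gold standard.
    True disease status is latent; each measure is characterised by a
    sensitivity and a specificity with informative priors built from
    external validation studies via their asymptotic sampling
    distributions. Inference is by multi-chain adaptive Metropolis MCMC on
    the logit scale, with split-chain Gelman-Rubin and effective-sample-size
    diagnostics, posterior predictive checks on the observed 2x2
    cross-classification, prior-perturbation sensitivity analysis, the
    Rogan-Gladen closed-form correction as a frequentist oracle, and a
    synthetic-data generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
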