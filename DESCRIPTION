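Package: adpm
Title: Multidimensional ODE-Based Modelling of Alzheimer's Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a multivariate dynamical disease-progression model of
    Alzheimer's disease in which the joint rate of change of cerebrospinal
    fluid biomarkers (total tau, amyloid-beta 1-42) and three cognitive
    traits (language, memory, praxis) is a linear velocity field with
    covariate effects, solved exactly through the matrix exponential.
    Observations enter through sigmoid link functions with Gaussian and
    right-censored Gaussian likelihoods and graded-response IRT scoring of
    cognitive items; diagnosis labels (CN, MCI, AD) enter through an ordered
    logit layer. Parameters are estimated by blocked adaptive Markov chain
    Monte Carlo with hierarchical priors on subject-level initial states.
    Includes subject forecasting and time-to-conversion prediction,
    velocity-field posterior summaries, a synthetic ADNI-like cohort
    generator, and evaluation machinery: leave-one-site-out cross-validation,
    AUROC, multi-class reliability diagrams with Beta-Binomial intervals,
    and decision-curve analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    coda,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
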