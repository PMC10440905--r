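Package: nofonesim
Title: Simulation and Causal Analysis of Aggregated N-of-1 Trials with
    Carry-Over
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates series of N-of-1 crossover trials from a causal
    directed acyclic graph with time-varying linear structural equations,
    exponential-decay treatment carry-over (wash-in/wash-out), a Wiener-process
    baseline drift, and two participant drop-out mechanisms, emulating a
    multi-crossover study on chronic nonspecific low back pain. Provides five
    estimators of the average treatment effect difference: a naive sample-mean
    contrast, covariate-adjusted ordinary least squares, a carry-over adjusted
    parametric model (COAPM) with R-squared grid search over wash-in/wash-out
    parameters, G-estimation of a structural nested mean model using
    generalized estimating equations with independence or AR1 working
    correlation, and linear-Gaussian Bayesian-network estimation with optional
    lag-1 time adjustment. A Monte-Carlo harness compares bias and efficiency
    of all methods across simulation scenarios and sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
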