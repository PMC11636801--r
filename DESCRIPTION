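Package: countspec
Title: Metaheuristic Specification Search for Count-Data Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, extensive hypothesis testing for count-data regression
    models such as crash-frequency (safety performance) functions. Searches over
    candidate contributing factors, variable transformations, random parameters
    with alternative mixing distributions (normal, uniform, triangular, gamma,
    Lindley), and probabilistic model type (Poisson, negative binomial,
    generalized Poisson). Each candidate specification is estimated by maximum
    simulated likelihood with Halton draws and pruned by a significance-driven
    repair step; specifications are selected by BIC (or AIC / log-likelihood)
    using discrete Harmony Search, Simulated Annealing, or discrete Differential
    Evolution. Includes a synthetic-data generator for recovery experiments,
    broom-style tidiers, and ggplot2 convergence plots.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
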