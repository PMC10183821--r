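Package: pikasign
Title: Multi-Sign Dynamic Occupancy Models with False-Positive Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits dynamic (multi-season) occupancy models to detection/
    non-detection surveys that record several distinct sign types (fresh
    scat, fresh haypiles, calls, sightings), each with its own true- and
    false-positive detection process on the logit scale. Ambiguity flags on
    individual observations anchor identifiability of false-positive rates
    by forcing the false-detection probability of unambiguous records to
    zero. The latent occupancy state follows an annual
    initial-occupancy/colonization/extinction process with park- and
    year-level random effects, and is marginalized out of the likelihood
    with a two-state forward recursion. Includes a survey simulator that
    emulates multi-park pika monitoring designs, Bayesian fitting by
    adaptive Markov chain Monte Carlo with Gelman-Rubin diagnostics and
    posterior predictive checks, three simplified comparison variants of
    the observation model, reverse step-wise AIC covariate screening, and
    derived summaries (finite-sample occupancy series, inverse-variance
    weighted trends, sign-specific detection-rate tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
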