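Package: trendrisk
Title: Occupancy- and Abundance-Based Population Trends and IUCN
    Extinction-Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating temporal trends of wildlife populations
    from multi-season survey data and translating them into IUCN Red List
    criterion A2 threat categories. Fits Bayesian single-species multi-year
    occupancy models with imperfect detection, negative-binomial mixed
    models for count indices, and binomial mixture models with latent
    negative-binomial abundance, using a compiled adaptive
    Metropolis-within-Gibbs sampler over marginalized likelihoods. Posterior
    draws are propagated into derived quantities (yearly occupancy and
    abundance indices, between-period declines, decline probabilities, and
    generation-length-scaled decline rates) so that credible intervals on
    threat categories reflect full parameter uncertainty. Includes a
    synthetic-data generator with known truth for validation, convergence
    diagnostics, and a pipeline that compares occupancy-based and
    abundance-based assessments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
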