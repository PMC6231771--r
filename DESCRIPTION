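Package: phenosync
Title: Within-Population Phenological Synchrony Under Climate Warming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how spring warming changes leaf-out and
    flowering synchrony among the individuals of a plant population.
    Includes environmental-driver computations (degree-day forcing,
    chilling hours, photoperiod, preseason temperature), cleaning and
    pixelization of PEP725-style phenological observation series,
    per-pixel synchrony statistics and regressions, a hierarchical
    Bayesian random-intercept regression with its own Gibbs sampler and
    Gelman-Rubin diagnostics, a degree-day-only null simulation, and
    analytics for twig-cutting experiments (trait estimation, ANOVA
    variance partitioning, variance components). A synthetic climate and
    phenology generator with the statistical structure the analysis
    assumes makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
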