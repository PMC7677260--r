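Package: sapflowhm
Title: Hierarchical Bayesian Modelling of Whole-Tree Sap Flow from
    Thermal-Dissipation Probes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links whole-tree sap flow density measured with Granier
    thermal-dissipation probes to vapour-pressure-deficit and light
    drivers of transpiration through an optimal stomatal-conductance
    process model embedded in a three-level Bayesian hierarchical model.
    Provides probe preprocessing (baseline detection, Granier
    conversion, quadrant-annulus aggregation), a time-lagged
    heteroscedastic Laplace likelihood with a heavy-tailed prior on the
    leaf-to-sapwood area ratio, a differential-evolution MCMC sampler
    with archive (DREAM-ZS style), Gelman-Rubin convergence diagnosis,
    uncertainty partitioning into parametric and measurement components,
    leave-one-day-out cross-validation, height regressions of the
    fitted leaf-sapwood ratios and time lags, and a seeded synthetic-data
    generator emulating the boreal Scots pine study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    zoo,
    lhs
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
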