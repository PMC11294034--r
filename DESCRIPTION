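Package: hawkipm
Title: Two-Sex Integrated Population Models for Long-Term Raptor Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, simulating and fitting two-sex, stage-structured
    integrated population models (IPMs) of territorial raptor populations monitored
    over many decades, motivated by long-term goshawk (Accipiter gentilis) studies.
    The package provides the stochastic two-sex projection model (five female and six
    male stages with male immigration), an individual-based generator of the seven
    monitoring data sets (territory counts, sex- and age-specific breeder counts,
    brood success, fledgling counts, brood sex ratios, adult capture-recapture from
    moulted feathers, and dead recoveries of ringed nestlings), the seven component
    likelihoods and their joint Bayesian fit with temporal random effects via JAGS,
    transient elasticity and life-table response experiment (LTRE) analyses of the
    realized growth rate, a decomposition into environmental and demographic
    stochasticity, and density-dependence tests against a simulated
    exponential-growth null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
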