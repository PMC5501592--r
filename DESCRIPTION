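Package: batpva
Title: Climate-Driven Population Viability Analysis for Forest Bats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic age-structured (Leslie-type) population dynamics for
    fringed myotis (Myotis thysanodes) and similar long-lived, single-pup
    forest bats. Builds a four-class projection matrix from vital rates,
    computes growth rate, stable age distribution, and -10% finite-difference
    sensitivities and elasticities; links adult fertility to mean annual
    temperature and annual precipitation through a binary logistic model;
    turns climate inputs into per-year fertility drivers (stable, yearly
    series, linear step to a 2070 endpoint, range-wide ensemble pooling); and
    projects populations with Monte Carlo simulation under triangular
    demographic and environmental stochasticity. Includes synthetic-data
    generators for reproductive-status records, trending climate series, and
    occurrence-climate tables so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
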