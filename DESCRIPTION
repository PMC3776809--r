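Package: kdseason
Title: Seasonality Analysis for Multi-Site Disease Surveillance Counts
Version: 0.1.0
Authors@R:
    person("KD Seasonality Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tests for seasonal structure in monthly disease-count time
    series collected at many surveillance sites, developed around the
    global epidemiology of Kawasaki disease. Provides per-site
    seasonality tests (seasonal versus non-seasonal ARMA model
    comparison under AIC, autocovariance-spectrum peak significance
    against a red-noise background, and a case-reassignment Monte Carlo
    test of the largest monthly-mean difference), Hewitt's circular
    6-month rank-sum test with an exactly enumerated null distribution,
    and hemispheric sector aggregation of normalized monthly
    climatologies with a circular-shift Monte Carlo significance test.
    Includes a synthetic multi-site surveillance-data generator so the
    full pipeline is testable without access to consortium case data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
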