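Package: wetval
Title: Value Transfer for Wetland Ecosystem Services by Coupled
    Meta-Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the monetary value of wetland ecosystem
    services by benefit transfer. Derives service-function weights from
    analytic hierarchy process (AHP) questionnaires, scores wetland units
    against a land-type by service supply matrix, provides the standard
    direct valuation estimators (direct market, shadow project,
    equivalence factor, runoff regulation), and calibrates a log-linear
    coupling meta-regression on a database of published valuation cases
    with consumer-price-index normalisation, standardized-residual
    outlier rejection and leave-one-out cross-validation. Fitted models
    transfer per-hectare service values to a target wetland inventory and
    aggregate them into per-service and total values. A synthetic-data
    generator with known ground truth supports calibration tests and
    worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
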