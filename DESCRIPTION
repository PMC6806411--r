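Package: qsarpipe
Title: QSAR Model Building and Validation with Genetic Function
    Approximation
Version: 1.0.0
Authors@R:
    person("Tunde", "Adeyemi", email = "tunde.adeyemi@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for building and validating quantitative
    structure-activity relationship (QSAR) regression models from molecular
    descriptor tables. Implements Kennard-Stone training/test division,
    descriptor pretreatment (variance and correlation filters, min-max
    normalization), genetic function approximation (GFA) selection of
    multiple linear regression models under the Friedman lack-of-fit score,
    and the standard validation battery: leave-one-out Q2, external R2,
    Y-randomization with cRp2, standardized descriptor contributions,
    variance inflation factors, and a leverage-based applicability domain
    with Williams-plot outlier flags. Includes a synthetic descriptor/
    activity generator with known ground truth so every stage is testable
    without chemical structure input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
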