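Package: ivivctk
Title: In Vitro-In Vivo Correlation Toolkit for Multi-Component Oral Preparations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds level-A in vitro-in vivo correlations (IVIVC) for
    multi-component oral solid preparations such as traditional Chinese
    medicine tablets. Covers cumulative dissolution with sampling-replacement
    correction, Hill/Weibull/Makoid-Banakar dissolution model fitting and
    selection, dose-number based biopharmaceutics (BCS) classification,
    non-compartmental analysis, polyexponential unit-impulse-response fitting
    from intravenous reference data, numerical deconvolution to cumulative
    absorption curves (with a Wagner-Nelson cross-check), fitting and
    validation of four linear correlation forms with convolution-based
    plasma-profile prediction, prediction-error based internal and external
    validation, and BCS-class-weighted integration of multiple components
    into a single dissolution and plasma profile. Includes a synthetic-data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
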