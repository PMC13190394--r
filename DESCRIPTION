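Package: panelcausal
Title: Heterogeneous Panel Granger Causality with Bootstrap Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for heterogeneous panel Granger-causality analysis of
    balanced country-year panels: second-generation diagnostics
    (cross-sectional dependence tests, Pesaran-Yamagata slope homogeneity,
    CADF/CIPS panel unit roots), the Emirmahmutoglu-Kose lag-augmented VAR
    causality test with Fisher p-value combination and residual bootstrap
    critical values that preserve contemporaneous cross-sectional
    correlation, CS-ARDL mean-group long-run estimation with an
    error-correction representation, and a rule-based country-level
    causality typology. Includes a seeded synthetic-panel generator for
    factor-dependent integrated panels so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
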