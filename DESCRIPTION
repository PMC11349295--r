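Package: dcidep
Title: Scanning-Voltage DC Insulator-Based Dielectrophoresis Separation Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: In-silico model of direct-current insulator-based
    dielectrophoresis (DC-iDEP) separation of organelle populations in a
    sawtooth microchannel. Builds the 27-gate reference channel geometry,
    solves the electrostatic potential on a rasterized 2-D domain with a
    sparse finite-difference Laplace solver, derives the dielectrophoretic
    capture parameter and per-gate capture thresholds, simulates the
    multi-voltage scanning protocol that sorts particles by their
    electrokinetic-to-dielectrophoretic mobility ratio (EKMr), converts
    per-gate fluorescence intensity tables into normalized EKMr spectra,
    and compares two experimental conditions with a two-way ANOVA and
    Bonferroni-corrected post hoc tests. Includes a Brownian-dynamics
    particle tracker as an independent check of the capture predictor and
    a synthetic-data generator for vesicle populations and intensity
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    car,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
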