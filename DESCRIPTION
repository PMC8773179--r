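Package: gsisscreen
Title: Design and Analysis of Arrayed siRNA Screens for Glucose-Stimulated
    Insulin Secretion
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for arrayed siRNA screens of insulin
    secretion in 384-well format. Builds randomized triplicate plate
    layouts with reserved non-targeting and control siRNA wells, emits
    acoustic-dispenser (ECHO-style) picklists with source-sorted picking,
    scores every gene against on-plate non-targeting controls using the
    strictly standardized mean difference (SSMD) for both secreted-insulin
    signal and cell number, applies beta cut-offs with a cell-number
    viability filter, and integrates hits across basal, glucose-stimulated
    and IBMX-augmented secretion conditions. Includes a calibrated
    synthetic-screen generator for end-to-end testing and a delta-delta-Ct
    module for knockdown quantification by qPCR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
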