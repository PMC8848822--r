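Package: ncax
Title: Extended Necessary Condition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Necessity and sufficiency effect sizes from the empty corners of
    a bivariate scatter, estimated with free-disposal-hull (CE-FDH) and
    ceiling-regression (CR-FDH) ceiling lines. Significance of each effect is
    assessed by permutation, and the necessity-sufficiency difference by a
    bootstrap Z-test, with an interpretation layer that only reads a
    significant difference when the stronger effect is itself
    permutation-significant. Includes seeded synthetic-data generators with
    known empty-corner structure, CSV ingestion with listwise cleaning,
    TSV/JSON report serialization, a two-panel diagnostic plot, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
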