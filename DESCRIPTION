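Package: qams
Title: Single-Marker Quantification of Multicomponent HPLC Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of multicomponents by single
    marker (QAMS) in high-performance liquid chromatography: linear
    calibration fitting and inversion, relative correction factors (RCF)
    against an internal reference compound with ruggedness summaries across
    instruments, columns, temperatures and flow rates, peak identification
    by relative retention time, external-standard and single-marker
    quantification of herb contents, method-validation statistics
    (precision, repeatability, stability, spike recovery), and a
    ground-truthed synthetic chromatographic-run generator so the whole
    workflow is testable without instrument data. Ships reference data for
    the eleven polar components of Fructus Corni (Cornus officinalis) with
    loganin as the internal reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
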