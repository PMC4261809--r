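Package: seroscan
Title: Longitudinal Case-Control Microbiome Scans for Pre-Seroconversion
    Abundance Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting early-life gut-microbiome taxa whose
    relative abundance diverges between infants who later develop islet
    autoimmunity (cases) and matched controls, from longitudinal 16S rRNA
    amplicon count tables. Implements rarefaction and replicate-based
    abundance-reliability filtering, bootstrap-balanced Mann-Whitney
    differential-abundance testing with Benjamini-Hochberg correction over
    the full taxon count, logistic age-by-abundance interaction tests,
    sliding age-window scans with per-subject median downsampling,
    weighted Poisson calibration of coarse-platform species-group
    abundances against fine-platform species abundances with qPCR
    concordance checks, and leave-one-subject-out cross-validated AUC
    prediction of case status. A synthetic-cohort generator reproduces the
    statistical structure of a 76-infant monthly-sampled cohort so every
    stage can be exercised without access to restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    biomformat,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
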