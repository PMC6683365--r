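Package: surfmsi
Title: Label-Free Quantitative Mass Spectrometry Imaging of Exogenous
    Surfactant Peptides in Lung Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for locating and quantifying exogenous
    surfactant peptide analogs (SP-B and SP-C analogs of the synthetic
    surfactant CHF5633) in MALDI-TOF mass spectrometry images of lung
    sections.  Provides imzML input/output and ion-image extraction,
    density-mode batch correction with control-derived noise thresholding,
    a melittin-guided mixed-effects calibration workflow for absolute
    per-pixel quantification with confidence intervals, distance-from-border
    spatial profiles, section-level intensity summaries, and association of
    those summaries with per-animal physiological time courses (blood gases,
    lung compliance, ventilation pressures).  A synthetic-data module
    generates MSI sections, calibration slides and animal cohorts with the
    statistical structure the analysis assumes, so the whole chain is
    testable without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    xml2,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    car,
    EBImage,
    tibble,
    dplyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
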