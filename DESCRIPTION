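Package: vfscreen
Title: Visual-Field Deviation Maps, Defect Criteria and CNN-Based Glaucoma Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for Humphrey 24-2 static perimetry data: the 24-2
    test-point lattice with blind-spot handling and a rectangular grid
    embedding; a normative sensitivity model with total-deviation,
    general-height and pattern-deviation maps plus five-level probability
    categorization; global indices (mean deviation, pattern standard
    deviation, a simplified visual field index) and reliability-based record
    filtering; the clinical cluster criterion for glaucomatous field defects;
    a labeled visual-field simulator with glaucomatous archetypes and common
    confounders; compact convolutional classifiers for embedded deviation
    maps with ensemble fusion and Grad-CAM heatmaps; a printed
    pattern-deviation-plate renderer with capture simulation, cross
    localization and six-class symbol recognition; and ROC/AUC diagnostic
    statistics with DeLong confidence intervals and Youden operating points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
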