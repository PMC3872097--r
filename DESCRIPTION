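Package: bicepsQUS
Title: Quantitative Grayscale Echotexture Analysis for Biceps Tendon Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative diagnosis of long-head biceps tendinitis from B-mode
    ultrasound echotexture. Computes first-order grayscale statistics (min, max,
    mean, StdDev) over fixed physical-area regions of interest, applies the
    rule-based sheath-swelling/effusion reference criteria, classifies subjects
    by per-view StdDev cut-offs, and calibrates those cut-offs from labeled
    cohorts via empirical ROC curves, Hanley-McNeil AUROC standard errors, the
    Youden index, and univariate logistic screening. A synthetic-data module
    generates speckle-textured tendon images and simulated cohorts with the
    statistical structure the method assumes, so the full pipeline runs without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
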