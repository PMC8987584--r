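Package: anisohead
Title: Anisotropic Visco-Hyperelastic Brain Material Point Driver and
    Head Injury Risk Toolkit
Version: 0.6.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for head injury biomechanics. Evaluates a
    fiber-reinforced Mooney-Rivlin visco-hyperelastic brain material law at
    a material point under prescribed deformation histories, calibrates its
    parameters against reference response curves with a CORA-weighted
    rating objective, extracts Green maximum principal strain histories
    from marker-triad trajectories (the neutral density target method),
    and ships logistic and Weibull crash-induced injury index risk
    functions for cerebral contusion and acute subdural hematoma with
    ROC/AUC and confusion-matrix evaluation. A synthetic-data module
    generates marker fields, injury case tables, and signal pairs with
    controlled ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
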