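Package: cervia
Title: Quantitative Aceto-Whitening Analysis of Paired Cervicograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantitative visual inspection with acetic acid
    (VIA) screening from paired pre/post acetic-acid cervicograms: specular
    reflection removal, bit-plane cervix segmentation, fiducial-based rigid
    registration, clock-position slicing matching histopathology sectioning,
    extraction of five aceto-whitening predictors (color-ratio histogram mode
    shifts, green/blue channel dispersion, CIELAB a*, Haralick correlation of
    the saturation-difference texture), KNN/SVM/decision-tree training with
    holdout 10-fold cross-validation, and diagnostic agreement statistics
    (sensitivity, specificity, accuracy, Cohen kappa, ROC/AUC) with clock
    annulus visualization. A seeded synthetic cervicogram generator provides
    ground-truthed cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    class,
    e1071,
    rpart,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
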