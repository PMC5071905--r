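Package: echoquant
Title: Quantitative Echogenicity Indices for Thyroid-Nodule B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes quantitative echogenicity indices (EI) for thyroid
    nodules on B-mode ultrasound images: the trimmed nodule mean gray level
    (EI_N), differences against manually outlined thyroid parenchyma
    (EI_N-T) and strap muscle (EI_N-M), and a fully automatic
    ratio-normalised index (EI_(N-R)/R) built on an anterior outside
    reference selected without operator input. Includes polygon-to-mask
    rasterization for region outlines, reading of PNG and single-frame
    grayscale DICOM images, a speckle-phantom and cohort simulator with
    known ground truth, and the diagnostic-statistics workflow used to
    evaluate the indices: 2x2 diagnostic metrics, odds ratios with Woolf
    confidence intervals, Fisher's exact test, Cohen's kappa, ROC/AUC,
    uni- and multivariate logistic regression, and quartile risk grouping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
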