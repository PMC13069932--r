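Package: odhscore
Title: Optical-Density HScore Quantification for ERBB2 Immunohistochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies brightfield immunohistochemistry (IHC) field images by
    min/max-midpoint thresholding, measures mean stain intensity and percent
    stained area, and converts them into an optical-density HScore,
    log10(255/mean intensity) x (percent area + 1), aimed at resolving
    ERBB2 (HER2) IHC 2+ equivocal breast-cancer cases against FISH-confirmed
    status. Includes cohort-level decision analysis (empirical ROC with DeLong
    confidence intervals, Youden-index cutoff selection, Bonferroni-corrected
    cutpoint scans, pairwise group AUCs, logistic association), synthetic
    generators for field images with known ground truth and for cohorts with
    a prescribed group structure, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
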