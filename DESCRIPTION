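Package: tmascore
Title: Automated Tumour Segmentation and Immunohistochemical Scoring of
    Tissue Microarray Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing automated, superpixel-based tumour
    segmentation of breast tissue-microarray (TMA) spot images against
    manual tumour masks, and for measuring the downstream effect of
    segmentation differences on nuclear oestrogen-receptor (ER)
    immunohistochemistry scores. Provides a seeded synthetic TMA-spot
    generator with ground-truth masks and programmed ER scores, SLIC-style
    superpixel segmentation with a random-forest tumour classifier and
    spot-level cross-validation, a three-type taxonomy of pixel-level mask
    disagreements, colour deconvolution of haematoxylin/DAB staining,
    nucleus detection with Allred and Quickscore computation, and ordinal
    agreement statistics (observed agreement, Cohen's kappa,
    quadratic-weighted kappa, Bland-Altman analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    randomForest,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
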