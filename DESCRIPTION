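Package: cdtl
Title: Class-Decomposition Transfer Learning for Slice-Based Brain Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects disease progression from volumetric brain images by
    selecting informative 2D axial slices with gray-level co-occurrence
    matrix (GLCM) entropy, decomposing each class into k-means subclasses
    before classifier training, and transferring the trained model - body
    frozen, head replaced - from an easy base task (Alzheimer's disease
    versus cognitively normal) to a hard target task (stable versus
    progressive mild cognitive impairment). Includes subject-grouped
    stratified cross-validation, imbalance-aware oversampling, bootstrap
    AUC confidence intervals, and a synthetic-data generator producing
    texture phantoms and subclustered imbalanced image tasks for
    download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    jsonlite,
    yaml,
    cluster,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    mclust,
    withr
Config/testthat/edition: 3
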