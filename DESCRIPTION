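Package: shapefeature
Title: Surface-Shape Quantification of Amyloid PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies beta-amyloid PET/CT studies by surface-shape
    descriptors. A volume of interest is segmented from PET at a multiple
    of the non-zero-mean standardized uptake value; its surface sphericity
    is summarized by the cerebral amyloid smoothing score (CASS), the
    irregularity of a CT-derived brain mask by the brain atrophy index
    (BAI), and their product by the shape feature. Includes synthetic
    PET/CT phantoms with known geometric ground truth, and the cohort
    statistics used to evaluate such imaging biomarkers: Mann-Whitney
    tests, ROC analysis with DeLong comparison of paired curves,
    Youden-index cut-offs, Spearman rank correlation, and sweeps over the
    threshold multiple.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
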