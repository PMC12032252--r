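Package: dsrtkit
Title: Drug Sensitivity Scoring and Morphological Profiling for 3D Tumor Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for multi-dose drug sensitivity and
    resistance testing (DSRT) of 3D tumor models and for single-cell
    morphological profiling of Cell Painting images. Covers plate-map and raw
    luminescence ingestion, control-based percent-inhibition normalization,
    constrained four-parameter logistic dose-response fitting, closed-form
    drug sensitivity scores (DSS) and selective scores (sDSS) against a
    healthy-control model, Z-prime plate quality control, threshold-based hit
    calling with low-dose toxicity flags, minimum cross-entropy thresholding,
    marker-based watershed nuclei segmentation, propagation-based cell
    segmentation, a 300+ feature single-cell catalog with plate-wise DMSO
    standard scaling, UMAP embedding and hierarchical profile clustering, and
    the standard endpoint formulas (tumor volume, T/C ratio, 2^-ddCt,
    Student's t-test). Ships simulators for screens and microscope fields with
    planted ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    uwot,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
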