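Package: fusefinger
Title: Chromatographic and Infrared Fingerprint Fusion for Geographical
    Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A chemometric pipeline for authenticating the geographical
    origin of medicinal fungal material from multi-technique fingerprints.
    Implements correlation optimized warping (COW) with automated reference
    selection and segment/slack search for retention-time alignment of
    liquid-chromatographic fingerprints, Savitzky-Golay second-derivative
    preprocessing of ATR-FTIR spectra with exclusion of the diamond-crystal
    region, low-level (variable concatenation) and mid-level (PCA-score
    concatenation) data fusion with strict sample correspondence,
    multi-class PLS-DA by NIPALS with 7-fold cross-validated component
    selection, VIP scores and permutation testing, and model evaluation via
    Kennard-Stone splitting, confusion matrices and per-class sensitivity,
    specificity and efficiency. A seeded synthetic-fingerprint generator
    reproduces the study design (8 origins, paired inner/epidermis samples
    per sclerotium) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
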