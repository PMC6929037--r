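Package: radiomiR
Title: Radiomic-miRNA Association and Signature Evaluation for Breast DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end radiogenomic ("radiomiRNomic") analysis pipeline for
    breast cancer subtyping. Generates synthetic cohorts of pre/post-contrast
    MRI volumes with enhancing lesions and matched miRNA expression, segments
    lesions on subtraction images by seeded region growing, extracts a
    57-feature radiomic panel (intensity histogram, morphology, gray-level
    co-occurrence and run-length texture), reduces feature redundancy by
    Spearman correlation clustering with coefficient-of-variation
    representatives, maps Pearson correlations between imaging features and
    miRNA expression with significance filtering, and ranks single, paired and
    triple miRNA/imaging-feature signatures for Luminal A versus other-subtype
    classification with a radial-kernel SVM under Monte Carlo 60/40
    cross-validation and AUC scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
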