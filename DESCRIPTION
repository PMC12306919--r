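Package: iscrsa
Title: Intersubject Correlation and Representational Similarity Analysis for Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subject-based analysis of naturalistic fMRI experiments:
    pairwise intersubject correlation (ISC) of region-of-interest time series with
    Fisher z transformation and subject-wise bootstrap inference, intersubject
    representational similarity analysis (IS-RSA) relating neural similarity to
    behavioral similarity under the Anna Karenina model with Mantel-style subject
    permutation tests, Friedman and Wilcoxon comparisons of ISC across stimulus
    conditions, spherical ROI extraction at MNI coordinates from NIfTI volumes,
    scoring and reliability of a short perceived-stress scale, and a synthetic
    data generator with known ground truth for parameter-recovery and calibration
    testing of every stage.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
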