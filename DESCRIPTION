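Package: invisidec
Title: Multivoxel Decoding of Visible and Invisible Object Categories
Version: 0.1.0
Authors@R: person("invisidec", "developers", email = "invisidec@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a whole-brain region-of-interest
    multivoxel pattern analysis (MVPA) pipeline for decoding object category
    (faces versus tools) from fMRI response patterns under three presentation
    methods: fully visible viewing, continuous flash suppression (CFS) and
    chromatic flicker fusion (CFF). Provides event-related run-order
    optimization that minimizes first- and second-order category-transition
    predictability, a synthetic multivoxel data generator with planted,
    method-dependent category coding axes, behavioral exclusion rules
    (breakthrough trials, above-chance guessing runs, minimum-exemplar rule),
    cross-exemplar leave-one-run-out and cross-method linear SVM decoding
    scored as d-prime, and group-level inference with one-sided t-tests,
    Benjamini-Hochberg FDR and visible-ROI gating.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
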