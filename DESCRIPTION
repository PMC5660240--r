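Package: natisc
Title: Inter-Subject Correlation Analysis for Naturalistic fMRI with
    Companion Gaze, Physiology and Behavioural Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pairwise inter-subject correlation (ISC) analysis of BOLD
    time series for naturalistic (movie-watching) fMRI designs, including
    nuisance cleaning, Fisher-Z pair tensors, permutation-based one-group
    and between-condition inference with Benjamini-Hochberg FDR control,
    cluster-extent filtering and max-p conjunction. Ships a minimal
    first/second-level GLM with a canonical double-gamma HRF and
    threshold-free cluster enhancement (TFCE) under sign-flip
    permutations, an eye-gaze ISC pipeline (fixation detection, drift
    correction, windowed Gaussian heatmaps, permutation group tests), and
    ancillary statistics (framewise displacement QC, similarity
    permutation tests, TOST equivalence, Mantel tests, time-point-wise
    rating tests). A seedable synthetic-cohort generator with analytic
    ground truth makes every stage testable without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
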