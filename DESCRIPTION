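Package: mklconn
Title: Motor Functional Connectivity Biomarkers via Multiple Kernel Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A resting-state functional-connectivity analysis pipeline for
    two-group (patient versus control) BOLD studies: nuisance regression with
    motion, cerebrospinal-fluid and white-matter regressors plus their
    derivatives, linear detrending and narrow-band Butterworth filtering;
    seed-based correlation mapping with atlas parcellation and per-region
    principal-component feature reduction; per-region radial-basis-function
    kernels combined by a multiple-kernel-learning support vector machine with
    recursive kernel elimination, evaluated under a two-tiered leave-one-out
    cross-validation with peak-region majority voting; a balanced
    label-permutation null for classifier significance; complex-network
    analysis of proportionally thresholded connectivity graphs (degree, path
    length, small-world ratio, binary assortativity) with false-discovery-rate
    group comparisons; and voxelwise Welch t-statistic group maps with
    permutation cluster-extent correction. Includes a synthetic cohort
    generator with group-dependent region covariance so every stage is
    testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    RNifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
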