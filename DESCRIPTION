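Package: schicab
Title: A/B Compartment Annotation from Single-Cell Hi-C Contact Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates A/B chromatin compartments from individual sparse
    single-cell Hi-C contact matrices without imputation. A dropout-aware
    Gaussian block model over the raw contact matrix is segmented by Bayesian
    two-dimensional change-point detection (Metropolis-Hastings sampling over
    fixed-size change-point configurations), the resulting loci groups are
    collapsed to a weighted graph on observed-over-expected normalized data
    and bipartitioned by a spectral normalized cut, and the two sides are
    oriented into A and B compartments by correlation with CpG density.
    Includes planted-structure simulators (dropout, binomial downsampling,
    fixed-contact subsampling, band-preserving shuffle mixing), evaluation
    metrics (intersection, per-locus accuracy, binary compartment variance,
    stable/variable classification), a data-driven rule for choosing the
    number of change points, and a normalized-cut compartmental-strength
    statistic.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
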