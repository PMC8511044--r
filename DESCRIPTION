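Package: wmeclone
Title: Windowed-Expression Inferred CNV, Subclone Tracking and cfDNA
    Concordance for Longitudinal Single-Cell Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@wmeclone.dev",
           role = c("aut", "cre"))
Description: Infers copy-number structure from single-cell RNA-seq by
    trimmed windowed mean expression (uWME/WME/rWME), discovers tumor
    subclones by Kendall-tau-distance weighted-linkage clustering, tracks
    their fractional abundance across treatment time points, and tests
    concordance between single-cell expression and purity-corrected
    cell-free DNA copy ratios. Includes bin-matched background-subtracted
    gene-signature module scoring, the longitudinal statistical layer
    (rank-sum tests, two Cohen's d variants, Kendall tests, Bonferroni
    adjustment, treatment-phase grouping), a seeded synthetic cohort
    generator with implanted CNV subclones and matched cfDNA profiles,
    and readers/writers for MatrixMarket, TSV, GMT and YAML formats.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    uwot
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
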