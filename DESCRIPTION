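Package: exprqc
Title: Expression-Based Quality Control for Sequencing Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-level quality control for bulk and single-cell sequencing
    count matrices. Given a gene-by-sample count matrix and a phenotype sheet,
    computes per-sample summary statistics, counts distributions, mapped-read
    density on TPM or variance-stabilized scales, housekeeping-gene (GAPDH/ACTB)
    profiles, principal component analysis on z-scored and un-normalized data,
    multiple factor analysis with inverse-first-eigenvalue covariate weighting,
    agglomerative hierarchical clustering, Pearson and Spearman sample
    correlation matrices, and per-sample LOWESS fits of gene counts against GC
    content, to surface outlier samples and cross-sample contamination. Includes
    a negative-binomial count simulator with planted technical artifacts and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
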