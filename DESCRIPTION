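Package: pgxtriad
Title: Integrated Pharmacogenomic Association Analysis for
    Lymphoblastoid Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for cell-line pharmacogenomic
    studies that relate germline genotype, basal gene expression, and
    drug cytotoxicity (IC50) in multi-population lymphoblastoid cell
    line panels.  Provides dose-response logistic fitting and IC50
    extraction, SNP and sample quality control (call rate,
    Hardy-Weinberg exact test, minor allele frequency), genotype
    principal components for population-stratification adjustment,
    covariate-adjusted partial Pearson correlation scans with Wald
    tests and Storey q-values, window-based aggregation of association
    signals into SNP loci, and the three-way SNP-expression-IC50
    "triad" (integrated) analysis with cis/trans classification.  A
    synthetic-cohort generator with a ground-truth ledger supports
    calibration and power/recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    minpack.lm,
    splines,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
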