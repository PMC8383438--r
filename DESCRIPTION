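Package: atacdiff
Title: Differential Chromatin Accessibility Analysis for Sorted-Nuclei ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for case-control differential chromatin
    accessibility analysis of fluorescence-activated nuclei sorting (FANS)
    ATAC-seq data, modelled on cohort studies of neuronal versus non-neuronal
    nuclei in late-onset Alzheimer's disease. Provides ENCODE-style library
    complexity metrics (NRF, PBC1, PBC2) and sample-level quality filters, TMM
    normalization, iterative principal-component-based covariate selection,
    negative-binomial quasi-likelihood differential testing with sex-chromosome
    exclusion, genomic feature annotation of peaks, and permutation enrichment
    of differential sites within GWAS tag-SNP windows. A negative-binomial
    synthetic-data generator with planted ground truth (cell-type effects,
    sex-restricted disease effects, confounded technical covariates) makes
    every stage testable without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR,
    limma,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
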