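Package: methblocks
Title: Data-Driven Segmentation of Whole-Genome Bisulfite Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies spatially homogeneous, cohort-shared DNA methylation
    blocks from multi-sample whole-genome bisulfite sequencing (WGBS) count
    data. CpG sites are merged by adjacency-constrained agglomerative
    clustering under a binomial negative log-likelihood-ratio cost with a
    heavy-tailed genomic distance penalty; the resulting per-chromosome
    dendrogram is cut at a Bayesian Information Criterion selected
    resolution, and each segment is tested for a coherent (common) site-wise
    methylation level with a likelihood-ratio test. Includes readers and
    writers for Bismark coverage and bedGraph count files, a piecewise
    constant synthetic-data generator with graded noise injection for
    robustness evaluation, breakpoint-recovery metrics with bootstrap
    confidence intervals, and annotation enrichment via Fisher's exact test
    with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
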