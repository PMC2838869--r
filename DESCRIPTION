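Package: laneseq
Title: Normalization and Differential Expression for Lane-Based mRNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene-by-lane read-count tables from
    multi-lane mRNA-Seq experiments. Implements per-lane scaling
    normalization (total-count, housekeeping-gene, and upper-quartile
    factors, all rescaled to a common grand total), full quantile
    normalization with integer rounding, and RPKM-style per-length
    expression measures. Differential expression between two biological
    conditions is tested per gene with a Poisson log-linear model using
    the scaling factors as offsets (likelihood-ratio and Wald t
    statistics), a delta-method t statistic on pooled counts, Fisher's
    exact test, and a Mantel-Haenszel test stratified by flow-cell.
    Supporting tools build union-intersection gene models from transcript
    annotation, count uniquely mapped reads over them, correct
    gene-length bias by inverse-square-root-length weighting or
    fixed-length resampling, benchmark calls against a qRT-PCR gold
    standard with direction-aware ROC curves, assess Poisson
    goodness-of-fit across replicate lanes, and simulate realistic count
    data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    Matrix
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
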