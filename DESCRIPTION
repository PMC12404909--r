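Package: stresshypo
Title: Permutation-FDR Differential Expression and Co-Expression Network
    Analysis for Two-Group Tag-Seq Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested pipeline for two-group bulk Tag-seq designs:
    gene-level count filtering, library-size normalization with a voom-style
    log-CPM transform and precision weights, empirical-Bayes moderated t
    statistics with a permutation-based empirical false discovery rate (eFDR),
    signed-hybrid weighted gene co-expression network analysis (soft power
    selection by scale-free topology fit, topological overlap, module
    eigengenes, module membership, hub genes, eigengene-group regression),
    hypergeometric over-representation analysis on user-supplied gene sets,
    and Welch t / Cohen's d / Spearman-Holm phenotype statistics. Includes a
    negative-binomial simulator with planted differential expression and
    planted co-expression modules so the full pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
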