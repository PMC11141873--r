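Package: coexmotif
Title: Coexpression-Anchored Promoter Motif Enrichment Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end screen that nominates candidate transcriptional
    regulators of a seed gene from bulk RNA-Seq and promoter sequence alone.
    Genes are filtered for detectable expression (CPM and FPKM lower
    confidence bound), correlated with the seed gene by Spearman rank
    correlation, and the promoters of the correlated gene set are scanned for
    IUPAC consensus binding sites on both strands. Per-motif enrichment in
    correlated-set promoters versus all other expressed genes is tested with
    a semiparametric logistic generalized additive model that absorbs
    promoter GC content and length, with Benjamini-Hochberg false discovery
    rate control, and candidate target genes are ranked per motif by a
    rank-product of motif abundance and seed correlation. A fully
    deterministic synthetic-data generator (negative-binomial counts driven
    by a latent regulator, promoters with planted motif instances) makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    rtracklayer,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
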