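Package: coexnet
Title: Co-Expression Network and Functional Enrichment Analysis for Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis engine for gene co-expression studies on bulk RNA-seq
    compendia: Pearson correlation with p-values on log2(TPM + 0.25) matrices,
    Highest Reciprocal Rank (HRR) and Mutual Rank (MR) co-expression scores,
    MR-thresholded networks with distance-limited traversal and annotation
    keyword filtering, Fisher's exact functional enrichment (GO/KEGG/KOG/Pfam)
    with Benjamini-Hochberg FDR and GO DAG propagation, a negative-binomial
    Wald differential-expression stage with median-of-ratios normalization,
    exclusive-intersection (UpSet) set relations, exploratory clustering and
    PCA, and seeded synthetic-data generators so every stage is testable
    without downloads.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2 (>= 1.40),
    SummarizedExperiment,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
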