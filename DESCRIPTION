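Package: pcalign
Title: Principal-Component Alignment Analysis of Multi-Muscle RNA-Seq Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering condition-associated transcriptomic
    signatures by aligning genes with principal components of bulk RNA-seq
    expression matrices. Implements weighted read-to-transcript counting and
    TPM/CPM quantification, double-centering and singular value decomposition
    with per-gene projection z-scores and cosine correlations, the two-threshold
    gene-PC alignment rule, signed hypergeometric overlap enrichment between
    signatures, hierarchical clustering of fold-change profiles, pre-ranked
    gene set enrichment analysis with permutation FDR and leading-edge
    reporting, and total-least-squares fits of pairwise fold-change
    comparisons. A synthetic-data generator emulates a multi-muscle
    aging/rapamycin study design with planted signatures so the whole pipeline
    runs and is testable without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
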