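Package: dpgnet
Title: Functional Network Analysis of Divergently Paired Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies divergently paired (head-to-head) genes from gene
    coordinate tables, contrasts their Gene Ontology semantic similarity
    (Schlicker relevance kernel combined by rcmax.avg) against randomly
    sampled gene pairs, builds overlap and interaction networks of
    functional gene sets bridged by divergent pairs with greedy
    cohesiveness-based module detection, and computes absolute and
    relative pathway perturbation scores from expression data with
    permutation nulls. Ships seeded synthetic-data generators (genome,
    ontology, annotations, gene sets, expression) with known ground truth
    so the whole pipeline is testable end to end.
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
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    limma,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
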