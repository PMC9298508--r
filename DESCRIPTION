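Package: emfnet
Title: Cross-Domain Microbial Co-Occurrence Networks and Ecosystem
    Multifunctionality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of multi-domain (bacterial, fungal,
    archaeal) soil microbiome surveys under herbivore disturbance:
    rarefaction of OTU count tables to even depth, alpha diversity
    (Chao1, observed OTUs, Shannon, Gini-Simpson) and Bray-Curtis
    community similarity, thresholded Spearman co-occurrence networks
    within and across domains with Gephi-style topology summaries, a
    Z-score ecosystem-multifunctionality (EMF) index over seven
    support/regulation functions, per-OTU enrichment ratios, and
    permutation inference on distance matrices (PERMANOVA, Mantel,
    multiple regression on distance matrices). A synthetic-community
    generator with planted correlation blocks, planted enrichment and
    environmental gradients provides ground truth for every stage.
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
    tools,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
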