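Package: compactdm
Title: Compact Disease Models from Cross-Platform Expression Consistency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distills multi-platform case/control expression studies into a
    Compact Disease Model (CDM): per-probe Primary Consistency Scores from
    subset-wise Welch tests, gene-level evidence tiers built from cross-probe
    and cross-platform concordance rules, expression-matched functional
    enrichment with a permutation false discovery rate, offline literature
    semantic-tag enrichment, and hypergeometric scoring of interaction
    sub-networks around the distilled gene list. Includes seeded generators
    for synthetic multi-platform studies, gene-set collections, literature
    corpora and interaction networks so the whole pipeline is testable
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
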