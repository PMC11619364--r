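Package: spacerhost
Title: Plasmid Host and Host-Range Prediction from CRISPR Spacer Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts potential bacterial hosts for plasmids by matching CRISPR
    spacers to plasmid sequences. Spacers act as sequence records of past
    encounters between a bacterium and foreign DNA, so an exact spacer match on
    a plasmid names a candidate host. The package provides an ungapped
    multi-pattern matcher with Karlin-Altschul E-value filtering and self-hit
    removal, taxonomic concordance analysis between reported and predicted
    hosts, host-range grading on the six-grade scale of Redondo-Salvo et al.
    with mobility-stratified summaries, categorization of targeted plasmid
    features into backbone/transposon/functional classes, bipartite
    plasmid-family and PTU-family network construction with Cytoscape-ready
    export, and a seeded synthetic-fixture generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    igraph,
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
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
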