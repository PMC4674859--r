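Package: pathevents
Title: Gene and Pathway Interaction Networks from Text-Mined Molecular Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns literature-scale molecular event annotations in BioNLP
    shared-task standoff format into merged gene-pathway interaction
    networks. Recognizes pathway mentions with a configurable soft
    dictionary matcher, merges overlapping gene and pathway mentions,
    bridges pathway entities through a gene-only event extractor via a
    disguise/undisguise step, normalizes participants to Entrez Gene IDs
    and canonical pathway records, expands nested events into undirected
    interaction pairs, and augments the text-mined network with curated
    pathway-membership edges. Includes topological analysis (hubs by
    degree, bottlenecks by betweenness centrality, clustering and
    path-length statistics), precision / pseudo-recall / F1 evaluation
    with candidate-pair sampling, and a synthetic corpus generator with
    planted ground truth for end-to-end validation.
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
    parallel,
    purrr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
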