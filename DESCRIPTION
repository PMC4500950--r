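Package: chromotif
Title: Chromatin-State-Modified Regulatory Network Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds transcription factor to target regulatory networks from
    ChIP-seq peaks, DNase I hypersensitive sites and promoter annotations;
    labels genes with four broad chromatin states by a promoter fold-enrichment
    rule; discovers state-colored three-node network motifs against a degree-
    and state-preserving edge-swap null model; tests mutual exclusivity of
    chromatin state compositions; quantifies feedforward-loop structure and
    state changes between two cell conditions; and prioritizes candidate genes
    with a state/structure change scoring scheme. Ships a synthetic-data
    generator so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
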