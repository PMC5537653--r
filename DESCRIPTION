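Package: viromenet
Title: Protein Similarity Networks and Comparative Genomics of Prophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative genomics of temperate phages and prophages built
    around reciprocated protein similarity networks. Implements an affine-gap
    Smith-Waterman aligner with Karlin-Altschul statistics for all-vs-all
    proteome comparison, reciprocal-hit network construction with
    connected-component clustering and summary statistics, cluster-based
    function transfer to hypothetical proteins, DNA methyltransferase
    catalytic-motif scanning with replication-module proximity, tRNA-anchored
    attachment-site (attL/attR) direct-repeat detection, and per-prophage
    genome statistics. A seeded synthetic-data generator produces protein
    families at controlled pairwise identity and host replicons with planted
    prophages so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
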