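Package: homoclust
Title: Homologous Protein Clustering with Similarity Graphs, Louvain
    Communities, and Sequence Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clusters protein sequences into homologous families by
    building a similarity graph from semi-global pairwise alignment
    statistics, detecting communities with a deterministic sequential
    Louvain modularity optimizer, and scaling to large collections through
    an iterative batch-clustering and sub-cluster merging scheme. Includes
    a flat-file cluster membership store with best-match queries,
    k-mer-distance sequence similarity networks for annotation support,
    and a synthetic-data generator with planted homologous families.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
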