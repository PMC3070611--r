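Package: pathminer
Title: Mining Chemoresistance-Associated Pathways in Integrated Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Integrates directed gene and protein interaction tables into a
    single deduplicated biological network, condenses cyclic regulatory
    relationships into supernodes so simple-path search is well defined,
    enumerates k-shortest simple paths between seed genes with Yen's
    algorithm, scores candidate pathways by aggregating per-gene
    differential-expression z-scores, intersects pathway sets between two
    conditions by gene-symbol correspondence, and ranks genes by scaled
    betweenness and degree centrality on a reference network. Ships a
    synthetic-data generator with planted differential pathways so every
    stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
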