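Package: acumine
Title: Association-Rule and Network Mining of Acupoint Prescription Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining transaction-style acupoint prescription corpora:
    acupoint name standardization against WHO-style codes, frequency and
    co-occurrence statistics, Apriori association-rule mining with
    support/confidence/lift, weighted co-prescription network construction with
    degree, betweenness, closeness and eigenvector centrality, clustering
    coefficient and average path length, small-world assessment against an
    Erdos-Renyi null ensemble, k-core decomposition, community detection,
    force-directed layout, and centrality/k-core based selection of a core
    acupoint combination. Includes a synthetic corpus generator with a planted
    core pair and cluster-structured co-selection so the whole pipeline can be
    validated by parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
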