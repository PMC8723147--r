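Package: coexrank
Title: Critical-Gene Prioritization from Co-Expression Networks via Graph
    Embedding and Explainable Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates differential-expression results with a weighted gene
    co-expression network to rank disease-relevant "critical genes" that need
    not themselves be differentially expressed. Builds a topological overlap
    matrix (TOM) from expression data, embeds the network into a
    low-dimensional coordinate space with a first-order negative-sampling
    embedding, trains explainable classifiers (logistic regression, random
    forest, gradient-boosted trees) to find the embedding dimensions that
    separate high-fold-change "impact" genes from the rest, and ranks genes
    by their proximity to impact genes in that subspace. Includes a TOM
    edge-weight neighbor-gene baseline, embedding quality checks against
    Louvain network modules, hypergeometric overlap tests, trait correlation
    summaries, and a synthetic-data generator with planted modules and
    planted regulator genes for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    randomForest,
    xgboost,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
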