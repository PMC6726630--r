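Package: complexeval
Title: Benchmarking Protein-Complex Detection Against Gold-Standard Complex Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the output of protein-complex detection algorithms
    against curated gold-standard complex catalogues. Implements the full
    family of bipartite overlap criteria used in this literature: the
    clustering-wise sensitivity, positive predictive value and accuracy
    (SN/PPV/ACC); the Jaccard-thresholded PrecisionN/RecallN/F-measureN;
    the maximal matching ratio (MMR) from maximum-weight bipartite matching
    on the neighborhood-affinity graph; threshold Precision/Recall/F;
    matching-based Precision+/Recall+/F-measure+ from maximum-cardinality
    matching; the composite MMR + F-measure+ score and its threshold-free
    area-under-curve form (AUMF), plus AUPR and AUPR+ precision-recall
    areas. Also provides cross-method consensus via k-partite maximal-clique
    integration (union/intersection), size, protein-identifier and
    reliability filters, plain-text cluster-file input/output, and seeded
    synthetic generators for gold standards, pathological detected-cluster
    sets and planted-complex interaction networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
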