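Package: mlnalign
Title: Pairwise Global Alignment of Multilayer Networks via Node Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise global network alignment (PGNA) for multilayer
    networks. Two attributed edge-list networks (intralayer edges carry a
    layer identifier, interlayer edges a dedicated one) are flattened to a
    typed-edge representation, node embeddings are learned with
    second-order biased random walks fed to a skip-gram model, a cosine
    similarity matrix is built (or supplied externally), a greedy
    one-to-one node mapping is extracted from it and refined by
    Jaccard-guided permutations. Includes a scale-free synthetic benchmark
    generator with duplication/divergence probabilities and noisy
    counterparts, and an evaluation suite (node correctness, alignment
    score, ROC/AUC, F1 variants, MCC, one-way ANOVA from group summaries,
    McNemar's test with continuity correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
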