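Package: dualcoexp
Title: Cross-Kingdom Co-Expression Network Analysis for Dual RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression modules separately for a host
    plant and its fungal symbiont from dual RNA-seq count matrices, links the
    two module sets into a bipartite cross-kingdom correlation network,
    extracts key genes, and associates modules with quantitative growth
    traits. Includes log2-CPM normalisation, factorial response
    classification of genes (cultivar, conserved mycorrhizal, conserved
    isolate, genotype-by-genotype interaction), soft-thresholded adjacency,
    topological overlap, dynamic branch cutting, module eigengenes and
    merging, a random-relabelling permutation null for the cross network,
    and a negative-binomial simulator that plants known module structure,
    factorial effects and trait loadings for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    Matrix,
    mclust,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
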