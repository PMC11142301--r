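Package: modpres
Title: Co-Expression Module Detection and Preservation Analysis for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare weighted gene co-expression networks between
    two single-cell RNA-seq conditions. Implements cell and gene quality
    control, log-normalization, variable-gene selection, PCA with a
    variance-based dimension heuristic, graph clustering, marker-based
    cell-type assignment, stratified diversity-preserving down-sampling to
    equalize group sizes, soft-thresholded adjacency and topological-overlap
    module detection in a reference condition, permutation and median-rank
    module preservation statistics in a test condition, and topological
    comparison of non-preserved module sub-networks (connectivity rank
    correlation, per-gene two-sample z-scores, top unique edges) together
    with local hypergeometric over-representation analysis. A synthetic-data
    generator with planted cell types and planted preserved or perturbed
    modules provides ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    yaml,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
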