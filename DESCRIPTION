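Package: weakties
Title: Protein Complex Detection in Interaction Networks via the Weak
    Ties Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects protein complexes in protein-protein interaction
    networks by exploiting the weak ties effect: edges joining
    topologically dissimilar proteins carry a high "bridgeness" computed
    from maximum-clique sizes, bridgeness is turned into edge weights, a
    truncated walk polynomial yields a pairwise similarity matrix, and
    thresholding that matrix produces a reliable virtual network whose
    maximal cliques are complex cores; attachments are recruited around
    each core by an average-closeness rule. Includes edge-percolation
    diagnostics (giant-component fraction and normalized susceptibility),
    the standard complex-evaluation metrics (neighborhood-affinity
    F-measure, coverage rate, hypergeometric enrichment, geometric
    accuracy, separation), synthetic core-attachment network generators
    with planted ground truth, and a robustness harness over randomly
    altered union-of-clique test graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    igraph,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
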