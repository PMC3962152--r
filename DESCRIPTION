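Package: hubnet
Title: Hub-Gene Prioritization from Protein Interaction Networks with
    Expression Meta-Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for confidence-scored protein-protein
    interaction networks of the kind exported by the STRING database.
    Builds a high-confidence interaction network from a weighted edge
    list, characterizes its topology (degree-distribution power-law fit,
    clustering coefficient, characteristic path length, diameter),
    prioritizes hub genes as the intersection of the top nodes under
    degree and betweenness centrality rankings, partitions the network by
    k-means on adjacency rows with a square-root-of-n/2 cluster-count
    rule, runs hypergeometric over-representation tests against
    user-supplied gene sets with Benjamini-Hochberg adjustment, and
    classifies hub genes as under- or over-expressed by combining
    gene-rank percentiles from two two-group expression datasets.
    Includes generators for scale-free synthetic networks and paired
    two-group expression data with planted differential genes, and a
    bundled summary table of published differential-expression results
    for NOTCH1-interactome hub genes in T-cell acute lymphoblastic
    leukemia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
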