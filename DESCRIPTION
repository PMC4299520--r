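Package: geneorderdist
Title: Distributed Gene Order Distances for Prokaryotic Genome Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates genome-wide gene order divergence between circular
    prokaryotic genomes by a Monte Carlo "distributed gene order" distance:
    repeatedly drawing small sets of well-separated orthologs and testing
    whether they occur in the same circular order in both genomes. Provides
    saturation corrections (an adapted Jukes-Cantor logarithm, its Tajima
    falling-factorial series, and the simple -ln(1-D) transform), reciprocal
    best hit orthology from tabular similarity hits, ortholog gene content
    distances, replicate neighbor-joining trees with node support, agreement
    subtrees, a hierarchical ranked-pair tree builder, and a genome
    rearrangement simulator for end-to-end validation on synthetic data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
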