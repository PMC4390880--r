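Package: arcogkit
Title: Phylogenomic Affinity Analysis over Clusters of Orthologous Genes
Version: 0.1.0
Authors@R: person("arcogkit", "developers", role = c("aut", "cre"),
    email = "arcogkit@example.org")
Description: Tools for tree-based phylogenomic analysis of prokaryotic
    genome collections organised into clusters of orthologous genes
    (COGs/arCOGs): relative genome weighting by branch-length distribution
    over a rooted species tree, weighted clade-representation statistics
    over phyletic patterns (core-gene selection, gene-tree candidate
    selection, exclusively-shared-gene screening), alignment-site filtering
    by gap fraction and column homogeneity, automated quantification of a
    focal clade's phylogenetic affinity across large sets of gene trees
    with topology-support classification, and a synthetic-data generator
    that emulates all pipeline inputs for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
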