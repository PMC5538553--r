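Package: crstool
Title: Phylogenetic Scoring and Annotation Statistics for Conserved RNA Structures
Version: 0.1.0
Authors@R:
    person("RTH", "Tools", email = "crstool@example.org", role = c("aut", "cre"))
Description: Tools for ranking candidate conserved RNA secondary structures in
    structure-annotated multiple alignments. Implements a three-model
    phylogenetic log-odds statistic (structured base-pair model versus
    conserved and neutral single-nucleotide models, evaluated by Felsenstein
    pruning on a tree) with thermodynamic weighting of base-pair contributions
    from a partition-function model, dinucleotide-preserving and GC-matched
    phylogenetic null alignments with GC-binned false-discovery-rate
    estimation, stratified genomic-interval enrichment tests, expression and
    transcript-stability calls, structure-probing concordance, and seeded
    synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
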