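Package: cophylointron
Title: Co-Phylogenetic Analysis of Mitochondrial Group I Introns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detection and characterization of group I introns in
    mitochondrial cox1 genes, and tests of their mode of transmission.
    Maps cox1 sequences against an intronless reference CDS to locate
    insertions, scans introns for LAGLIDADG homing-endonuclease open
    reading frames, and asks whether introns co-diverged with their host
    genes ("co-speciation") or moved horizontally. Includes a compact
    maximum-likelihood phylogenetics engine (GTR-family models with
    discrete-gamma rate variation and invariant sites, Felsenstein
    pruning, NNI/SPR hill-climbing search), reciprocal approximately
    unbiased (AU) topology tests via multiscale RELL bootstrap, a
    non-parametric Huelsenbeck-Bull likelihood-ratio test of topological
    congruence with a bootstrap-and-reassociate null, and a
    reimplementation of the ParaFit global and per-link co-speciation
    permutation tests on principal coordinates of patristic distances
    with Lingoes correction. A synthetic-data module simulates host
    trees, vertically or horizontally transmitted intron trees, and
    sequence alignments so that every stage of the pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
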