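Package: phylochar
Title: Parsimony Character Tracing and Phylogenetic Signal Tests for
    Discrete Ecological Characters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping discrete ecological characters (such as
    bathymetric depth classes and chemosynthetic habitat categories) onto
    molecular phylogenies.  Implements Fitch and Sankoff parsimony with
    most-parsimonious-reconstruction (MPR) state sets and equivocal-branch
    flags, a randomization test that compares the observed parsimony length
    against a null distribution of lengths on random tree topologies,
    monophyly classification of named groups, uncorrected pairwise sequence
    divergence, GTR+I+G log-likelihood evaluation on fixed topologies, and a
    synthetic-data generator (Yule trees, Mk characters, GTR+I+G sequences)
    with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    phytools,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pracma,
    Matrix,
    optparse
Config/testthat/edition: 3
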