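Package: codonLoss
Title: Pseudogene Detection, Shared-Indel Loss Mapping and Branch-Model
    Selection Tests for Coding Sequences
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying gene loss in protein-coding genes across a
    species phylogeny. Detects open-reading-frame disruptions (insertions,
    deletions, premature stop codons) in aligned coding sequences relative
    to a functional reference frame, maps shared disruptions onto a rooted
    species tree under a Dollo (no-regain) model to count independent
    pseudogenization events, and fits Goldman-Yang codon substitution
    models with branch-specific dN/dS (omega) to test for relaxed selection
    on designated foreground lineages via likelihood-ratio tests. Includes
    a codon sequence simulator with branch-specific selection pressure and
    planted loss events so the whole pipeline can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
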