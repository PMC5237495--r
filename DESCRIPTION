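Package: circMSA
Title: Rotation Refinement for Multiple Circular Sequence Alignment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes, for a set of circular DNA or protein sequences, the
    per-sequence rotations (cyclic shifts) that best linearise the set before
    conventional multiple sequence alignment. Pairwise rotations are found by a
    blockwise q-gram search with spacer-based refinement and cyclic edit
    distance; a neighbour-joining guide tree then orders a rotation-aware
    progressive profile alignment that propagates and refines rotations across
    profiles. Includes a Jukes-Cantor family simulator with recorded
    ground-truth rotations, standard alignment quality measures, and
    Robinson-Foulds tree comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, Biostrings, ape, phangorn, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Alignment, MultipleSequenceAlignment, Phylogenetics, Software
RoxygenNote: 7.3.3
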