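Package: nanoindent
Title: Quasi-Static Nanoindentation of Graphene/Phospholipid Composites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds atomistic models of bilayer-graphene/DPPC composite films
    and a capped zigzag carbon-nanotube tip, drives a displacement-controlled
    quasi-static indentation protocol with conjugate-gradient relaxation at
    every step, and analyses the mechanical and electronic response: adhesion
    energy between the graphene sheets and the phospholipids, per-atom local
    stress maps from energy-density changes, and Mulliken population analysis
    over a tight-binding surrogate. The molecular-mechanics engine is a
    compact AMBER-style force field with exact per-atom energy partitioning,
    implemented in C++ for speed.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
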