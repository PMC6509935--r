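Package: fachkrec
Title: Boolean Network Model of the Fanconi Anemia and Checkpoint
    Recovery Pathways
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synchronous Boolean network modelling of the interplay
    between the Fanconi anemia (FA/BRCA) DNA interstrand-crosslink
    repair pathway, the G2/M DNA-damage checkpoint, and the checkpoint
    recovery (CHKREC) machinery.  Ships the 25-node FA-CHKREC logical
    model as a built-in, annotated rule set; provides a parser and
    serializer for plain-text Boolean rule files (BoolNet-style
    "targets, factors" and a unicode dialect), deterministic synchronous
    dynamics with exhaustive attractor enumeration over the full
    2^25 state space (compiled functional-graph engine with basin
    sizes), in-silico knockout / constitutive-activation / interaction
    removal perturbations with single- and double-mutant screens,
    classification of attractors into cell-cycle arrest (CCA),
    cell-cycle progression (CCP) and progression-with-damage-adaptation
    (CCP-DDA) phenotypes, and derivation of the signed regulatory
    interaction graph from the logic with witness contexts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
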