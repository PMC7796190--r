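Package: chiralhh
Title: Chirality-Aware Modelling of Heterochiral Hammerhead Ribozyme Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and conformational analysis of mixed-chirality (D-/L-RNA)
    hammerhead ribozyme-substrate complexes. Provides ideal A- and B-form duplex and
    hammerhead scaffold generators, mirror (Z-negation) operations with D/L chirality
    classification and validation, enantiomerization of torsion/improper force-field
    parameter tables with a torsion-energy evaluator, Watson-Crick pair detection and
    restrained refinement, Kabsch superposition with explicit reflection handling, and
    per-residue conformational descriptors (backbone torsions, glycosidic chi,
    Altona-Sundaralingam pseudorotation, sugar-pucker classes) with ensemble statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    bio3d,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
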