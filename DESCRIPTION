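Package: fatsurf
Title: Fatgraph Models of Protein Domain Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds twisted ribbon-graph (fatgraph) models of protein domains
    from backbone coordinates and hydrogen bonds, and computes the topological
    invariants of the associated surface: Euler characteristic, number of
    boundary components, orientability and modified genus. Hydrogen bonds are
    inferred with the Kabsch-Sander electrostatic model or read from DSSP
    files; every alpha-carbon linkage and hydrogen bond is labelled twisted or
    untwisted from the relative orientation of the planar peptide-unit frames,
    yielding a two-letter secondary-structure annotation (the flip sequence).
    Includes the four basic fatgraph modifications with a robustness probe,
    idealized secondary-structure and random-fatgraph generators for property
    testing, and Smith-Waterman flip-sequence similarity scoring with
    sensitivity-calibrated nearest-level classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
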