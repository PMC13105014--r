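Package: crossbeta
Title: Geometry of Cross-Beta Amyloid Fibril Polymorphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative geometry of helically symmetric cross-beta amyloid
    fibrils. Converts refined helical twist and rise to apparent cross-over
    distances and back, evaluates a geometric twist-strain model relating
    ordered-segment length and cross-over distance to intermolecular spacing
    at segment ends, reads atomic fibril models (PDB/mmCIF) and organizes
    them into subunits and layers with a fitted growth axis, annotates
    backbone torsion angles, beta-strand segments by an alternating-sides
    hydrogen-bond rule, inter-subunit contacts, salt bridges and molecular
    axis (herringbone) angles, compares polymorphs by range-restricted
    superposition RMSD and circular torsion differences, and generates
    synthetic in-register cross-beta fibril models with known twist, rise,
    symmetry and strand layout for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
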