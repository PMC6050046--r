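Package: ftszlat
Title: Lateral Interfaces and Z-Ring Incorporation Models for FtsZ
    Protofilaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural and stochastic analysis of lateral
    interactions between protofilaments of the bacterial tubulin homolog
    FtsZ.  Reads and writes macromolecular coordinates (PDB and mmCIF),
    expands crystallographic screw symmetry (P6522 built in) into helical
    filament models, extracts screw-axis parameters (twist, rise, pitch)
    by least-squares rigid-body superposition, quantifies protofilament
    lateral interfaces (Shrake-Rupley solvent-accessible surface area,
    buried interface area, contact residues, salt bridges, charge
    complementarity), assembles antiparallel protofilament sheet models
    by iterative superposition, and implements a stochastic model of the
    incorporation of protofilaments carrying laterally disruptive
    subunits into the cytokinetic Z-ring, with an exact enumeration
    oracle for small instances.  Synthetic fixture generators (idealized
    helices, screw-symmetric crystal frames, toy dimers with planted
    contacts) support fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
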