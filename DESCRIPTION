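Package: vmtissue
Title: Vertex-Model Simulation of Multicellular Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A physics-based vertex-model engine for multicellular tissue
    biophysics. Cells are represented as polygonal surfaces (2D) or
    polyhedral bodies (3D) in a shared mesh; all model physics resolve to
    forces on vertices, which move by overdamped energy-gradient dynamics.
    Parameterized force models ("actors": area, perimeter and volume
    constraints, edge tension, adhesion, traction, normal stress) bind
    additively to mesh objects or object types. Dynamic-topology quality
    operations (vertex merge and split, surface and body demote, vertex
    insert) implement T1, T2 and T3 transitions from local force and
    geometry criteria. A minimal bead-spring particle subsystem models
    extracellular-matrix fibers and integrins for hybrid vertex-particle
    models. Includes demonstration pipelines for differential-adhesion
    cell sorting and single-cell migration over a fiber substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
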