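Package: csgmol
Title: Constructive Solid Geometry on Molecular Surfaces and Electrostatic Isopotentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact constructive-solid-geometry (CSG) operations on molecular
    solids and closed triangle meshes, evaluated by a breadth-first-search
    marching-cubes engine at arbitrary resolution. Builds solvent-excluded
    (Connolly) molecular solids from atomic coordinates via a regular
    (weighted Delaunay) triangulation, assembling atom spheres, toroidal
    spindles, tetrahedra and concave probe "cups"; interprets any closed
    triangle mesh (e.g. an electrostatic isopotential extracted from a scalar
    potential grid) as an exact solid by lattice classification and ray-parity
    voting; and composes all of these with union, intersection and difference.
    Downstream tools construct solid representations of ligand-binding
    cavities, extract connected fragments, and compare solids by enclosed
    volume (Surveyor's formula) and per-vertex displacement distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    parallel,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
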