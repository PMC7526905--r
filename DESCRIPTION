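Package: ellipack
Title: Ellipsoid Packing Analysis of Molecular Crystals via Persistent
    Homology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies molecular crystals whose centroid arrangements are
    affine transformations of the four basic cubic Bravais lattices
    (primitive, base-centered, body-centered, face-centered) by comparing
    persistence diagrams of the affinely normalized centroid motif against
    analytically grounded reference diagrams under the bottleneck distance.
    For identified crystals it estimates the radii of identical ellipsoids
    densely packed at the molecular centroids, and predicts those radii
    from single-molecule circular (ECFP/Morgan) fingerprints with a small
    feedforward neural network regressor.  Includes a synthetic-data
    generator that plants ground-truth lattice types, ellipsoid shapes and
    fingerprint-to-radii maps for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
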