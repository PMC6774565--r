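Package: ecmsuper
Title: Reduced-Order Superposition Modeling of Multi-Cell ECM Compaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates contractile cells embedded in a three-dimensional
    cross-linked extracellular-matrix (ECM) fiber network under overdamped
    mechanics (cortical tension, focal adhesions, lamellipodial protrusion,
    fiber stretch and bending), and predicts collective multi-cell ECM
    compaction from single-cell training runs. The reduction pipeline recasts
    the nonlinear dynamics in an augmented state space of coordinates plus
    force (auxiliary) variables, applies principal-component latent-variable
    reduction, identifies linear latent dynamics by least squares, and
    superposes per-cell latent models through the shared ECM state. Taylor
    and trajectory-piecewise-linear baselines, compaction metrics (slice-wise
    convex-hull volume, inter-cell elastic force, edge displacement), seeded
    fixture generators, and plain-text exporters (VTK legacy polydata, CSV,
    JSON) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
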