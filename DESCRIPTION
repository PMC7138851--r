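Package: grxfun
Title: Structure-Function Analytics for Glutaredoxin Catalysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis toolkit for glutaredoxin (Grx)
    structure-function studies. Implements the ping-pong two-half-reaction
    kinetic model with Dalziel-coefficient inference from initial-rate grids
    of the coupled NADPH/glutathione-reductase photometric assay, the
    pH-dependent iodoacetamide alkylation-protection assay for active-site
    thiol pKa determination (four-parameter Hill fits with group statistics),
    ratiometric roGFP2 plate-reader analysis (degree of oxidation, baseline
    correction, integrated dose-response), and binding-event analytics for
    glutathione anion diffusion trajectories (distance-cutoff event
    detection, bound fractions, sulfur geometry, occupancy density grids,
    pose clustering). Each analysis stage is paired with a calibrated
    synthetic-data generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
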