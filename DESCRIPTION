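Package: flapsense
Title: Strain-Based Rotation Sensing in Flapping Flexible Wings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spanwise strain in flapping rectangular plate wings with
    uniform or gradient flexural stiffness and tunable damping, encodes the
    strain at a dense grid of locations into probabilistic spike trains with a
    linear-nonlinear sensor model of campaniform sensilla, optimizes sparse
    sensor placement for detecting body rotations (SSPOC with an elastic-net
    constrained program), and quantifies rotation-detection accuracy,
    placement sensitivity and the modal structure of the strain field.  All
    inputs are generated internally from a configuration of wing, kinematic,
    encoding and optimization parameters; no external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
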