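Package: cardiofvm
Title: Finite-Volume Monodomain Simulation of Coupled Purkinje-Myocardium
    Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale cardiac electrophysiology simulator. Solves the
    monodomain reaction-diffusion model with the finite volume method on
    uniform hexahedral voxel grids (3-D myocardium) and one-dimensional
    Purkinje networks, coupled through resistive Purkinje-muscle junctions
    (PMJs). Time integration uses Godunov operator splitting with forward
    Euler or Rush-Larsen reaction sub-steps and a backward Euler diffusion
    solve via conjugate-gradient iteration. Includes pseudo-ECG computation
    for an unbounded volume conductor, PMJ anterograde-delay measurement
    with block and instability classification, factorial parameter-sweep
    generation with a concurrent batch dispatcher, and EnSight Gold and
    legacy VTK result writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
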