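Package: sinksource
Title: Sink- and Source-Limited Individual-Tree Growth Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the growth of an individual tree with coupled ordinary
    differential equations for stem radius, height, and non-structural carbon
    storage, driven by annual environmental forcing (temperature, PAR,
    atmospheric CO2). Growth switches between a carbon source limit
    (photosynthesis minus maintenance costs) and a carbon sink limit (the
    intrinsic capacity of the apical and lateral meristems), with a storage
    pool buffering the two. Includes adaptive Runge-Kutta integration with a
    trapezoidal cross-check, bounded nonlinear least-squares calibration of
    model parameters to stand height series, synthetic stand and forcing
    generators for simulation studies, and scripted numerical experiments
    (initial-condition sensitivity fans, source/sink regime maps, sink-off
    comparisons, CO2 counterfactuals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
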