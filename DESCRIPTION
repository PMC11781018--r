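Package: bogeom
Title: Gradient-Free Bayesian Optimization for Molecular Geometry Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates the global minimum on a ground-state potential energy
    surface and the most stable conical intersection between two electronic
    states without energy gradients, using Bayesian optimization with a
    Gaussian-process surrogate over Z-matrix internal coordinates.
    Provides analytic two-state diabatic benchmark surfaces with known
    optima, a conical-intersection penalty cost function, probability-of-
    improvement and upper-confidence-bound acquisition functions, a
    multi-start L-BFGS-B candidate-proposal scheme with an atomic-collision
    filter, patience-based termination rules, a uniform energy-noise model
    emulating measurements on noisy quantum hardware, and mirror-aware
    Kabsch RMSD evaluation against reference geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
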