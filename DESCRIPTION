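Package: sindyic
Title: Sparse Identification of Nonlinear Dynamics with Information-Criterion
    Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers governing equations of dynamical systems from
    time-series data by combining sparse regression over a combinatorially
    large library of candidate terms (sequential thresholded least squares and
    its ridge-regularized variant for partial differential equations) with
    simulation-based cross-validation and corrected Akaike information
    criterion (AICc) ranking. Each candidate model is classified as having
    strong, weak or no support relative to validation trajectories. Includes
    ground-truth simulators and synthetic-data generators for five canonical
    example systems (a one-dimensional polynomial system, a two-dimensional
    cubic oscillator, a discrete SEIR epidemic map, the Lorenz equations and
    Burgers' equation) plus sensitivity experiments over noise level,
    validation-set size and validation horizon.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
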