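Package: lampreysim
Title: Closed-Loop Neuromechanical Simulation of Lamprey Swimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular simulator for closed-loop anguilliform swimming. A double
    chain of sinusoidally coupled phase oscillators models the lamprey central
    pattern generator and drives calcium-gated Hill-type muscle segments on a
    three-filament spring-network body immersed in a two-dimensional viscous
    incompressible fluid (immersed boundary method on a uniform staggered grid,
    with a fast resistive backend for plumbing tests). Proprioceptive feedback
    from smoothed body curvature closes the loop in two functional forms,
    magnitude and directional. A metrics suite computes swimming speed, tailbeat
    amplitude and frequency, body wavelength, duty cycle, Strouhal number,
    neuromechanical phase lag, curvature and activation wave speeds, and cost of
    transport, and a synthetic-fixture generator provides traveling-wave
    kinematics and activation patterns with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
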