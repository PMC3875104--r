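Package: couplefde
Title: Fractional-Order Couple Dynamics: Caputo Solvers, Stability, and A
    Priori Bounds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a fractional-order nonlinear model of the feelings of
    two interacting individuals, posed with a Caputo derivative of order
    between 1 and 2 to model acceleration in feelings.  Provides a
    predictor-corrector (Adams-Bashforth-Moulton) solver for Caputo
    initial-value problems of order in (0, 1], a Mittag-Leffler evaluator
    used as an analytic oracle on linear problems, the order-reduction
    transformation of the couple model to a four-dimensional system,
    equilibrium computation by polynomial elimination, local stability
    analysis via fractional Routh-Hurwitz conditions and the
    eigenvalue-argument test, coupled Gronwall-type integral bounds and the
    associated a priori trajectory envelopes, seeded generation of
    romantic-style parameter scenarios, and a command-line interface that
    reproduces the reference simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
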