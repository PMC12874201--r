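Package: lsprkin
Title: Binding Kinetics and Calibration-Free Polymer Molecular Weight from
    LSPR Sensorgrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of label-free optical biosensor (LSPR/SPR) binding
    experiments on polyelectrolyte pairs. Fits pseudo-first-order association
    transients of dual-channel sensorgrams by nonlinear least squares
    (single- and double-exponential models), regresses observed rate
    constants against analyte concentration to obtain association and
    dissociation rate constants and the equilibrium dissociation constant,
    and determines the number-average molecular weight and degree of
    polymerization of an uncharacterized polyelectrolyte calibration-free
    from the ratio of rate-line slopes measured in the two orientations of
    the interaction. Includes a synthetic sensorgram simulator (reaction-
    and transport-limited) with known ground truth so the whole pipeline is
    testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
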