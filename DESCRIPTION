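Package: embolrheo
Title: Rheology and Reduced-Order Hemodynamics of Non-Adhesive Embolic Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constitutive viscosity modeling and reduced-order hemodynamics for
    non-adhesive liquid embolic agents (ethylene vinyl alcohol copolymers in
    DMSO such as Onyx-18 and Squid-12) used in endovascular embolization of
    arteriovenous malformations. Provides Sisko and Ostwald-de Waele
    shear-thinning viscosity laws with published constants, nonlinear
    least-squares fitting of flow curves, piecewise log-linear approximation,
    log-linear temperature interpolation of viscosity between laboratory
    (20 C) and body (37 C) temperature, detection of the nonmonotonic
    viscosity zone near 1/s, a seeded synthetic rheometry generator, a 1D
    Poiseuille resistance solver for a catheter plus AVM vessel network with
    shear-dependent viscosity, and a lumped plug-flow model of polymer warm-up
    along the intracorporeal catheter segment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
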