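Package: eccwater
Title: Four-Site Water Model Construction and Surrogate-Accelerated
    Parameterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building rigid four-site (TIP4P-family) water models
    from their six defining parameters: site geometry with a virtual charge
    site on the H-O-H bisector, molecular dipole and tetrahedral quadrupole
    moments, GROMACS topology export, and charge scaling for electronic
    continuum corrected (ECC) force fields. Implements the weighted
    mean-absolute-percentage-error cost function against experimental
    property targets (density isobar, nuclear dielectric constant,
    finite-size-corrected self-diffusion, first oxygen-oxygen RDF peak) and
    a three-phase optimization loop: bounded random-walk seeding,
    differential evolution, and refinement guided by a multilayer-perceptron
    surrogate that screens candidates before expensive property evaluation.
    A smooth synthetic property evaluator with a planted optimum allows the
    full loop to be exercised without a molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
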