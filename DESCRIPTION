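Package: memvisc
Title: Membrane Shear Viscosity from Equilibrium Diffusion Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts membrane shear viscosity from equilibrium trajectory
    data of membrane-embedded probes. Implements the Saffman-Delbrueck
    hydrodynamic models for lateral and rotational diffusion, finite-size
    (periodic-boundary) corrections for flat simulation boxes, time- and
    ensemble-averaged mean-squared-displacement estimation with diffusion
    coefficient fitting, four independent viscosity-inference routes with a
    cross-route consistency summary, Arrhenius temperature analysis, and
    composition trend statistics (cholesterol, acyl chain length and
    unsaturation). Ships a Brownian-dynamics generator of synthetic probe
    trajectories with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
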