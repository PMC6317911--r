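Package: piezodome
Title: Membrane Footprint Mechanics and Tension Gating of the Piezo Dome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum-mechanics model of the lipid membrane deformation
    ("membrane footprint") surrounding the dome-shaped Piezo ion channel.
    Computes minimum-energy axisymmetric membrane shapes under Helfrich
    bending elasticity and lateral tension, both in the small-gradient
    (Monge) approximation and by a full nonlinear arclength shape-equation
    solver valid at large curvature, for infinite membranes and finite
    clamped membrane compartments. From the dome and footprint energies it
    derives tension-dependent gating energies, two-state open-probability
    curves, and tension sensitivities of mechanosensitive gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
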