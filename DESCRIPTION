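Package: gridqsar
Title: Grid Molecular-Field 3D-QSAR Modelling and Virtual Screening
Version: 0.1.0
Authors@R:
    person("gridqsar", "developers", email = "gridqsar@example.org",
           role = c("aut", "cre"))
Description: A CoMFA-style 3D-QSAR toolkit for congeneric small-molecule
    series: rigid template alignment, steric (Lennard-Jones) and
    electrostatic (Coulomb) probe interaction fields on a rectangular
    grid, invariable-descriptor filtering, sphere-exclusion train/test
    splitting, stepwise-forward multiple linear regression with
    leave-one-out q2, external pred_r2, F statistics and Y-randomization
    Z-scores, and library screening with a signed applicability-domain
    extrapolation score. Includes a synthetic congeneric-series generator
    with planted linear truth so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
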