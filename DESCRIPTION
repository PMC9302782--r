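Package: avghemo
Title: Arteriovenous Graft Hemodynamics: Geometry Parametrization, Lumped
    Distal Boundary Models and Disturbed-Flow Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for modelling hemodialysis arteriovenous
    graft (AVG) hemodynamics. Builds parametrized idealized and
    centerline-based AVG lumen geometries with clinical trimming and
    flow-extension rules; implements three distal boundary-condition
    models of the peripheral vasculature (zero-flow, arteriovenous
    coupling, and arteriovenous coupling with an adaptive collateral
    resistor) together with their total-peripheral-resistance fitting and
    parameter-splitting rules; simulates the full graft flow loop with a
    lumped resistance-inertance network surrogate; and computes the
    disturbed-flow and wall-shear-stress metric suite (TAWSS, peak WSS,
    oscillatory shear index, threshold area fractions, Reynolds
    decomposition perturbation RMS and its cross-sectional median
    profile). Includes seed-deterministic synthetic fixture generators
    (pulsatile inlet waveforms, toy centerlines, WSS and velocity field
    time-series with analytically known metric values) so every component
    can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
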