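Package: airwayflux
Title: Lumen Morphometrics and Flow Energy-Loss Accounting for Compressed Airways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies progressive tracheal compression and its aerodynamic cost.
    Extracts centerline-normal cross-sectional area profiles from triangulated
    lumen surface meshes, computes constriction metrics (minimum area, ratio and
    constricted-segment length), reduces time-resolved planar flow samples to
    station-wise energy flux, cumulative energy loss and airway resistance
    profiles, and fits an orifice-type power law relating pressure loss to
    flowrate. Includes a parametric generator of stenosed airway surfaces and
    analytic flow fields with known injected losses for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
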