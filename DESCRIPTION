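Package: mechchem
Title: Mechanochemical Model of the Cardiac Calcium-Tension Relationship
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and fits a mechanochemical model of cardiac sarcomere
    contraction in which mechanical tension in the thin filament strengthens
    calcium binding to troponin, boosting the apparent cooperativity of the
    calcium-tension relationship well beyond the intrinsic chemical level.
    Provides the single-overlap sarcomere geometry, integration of the
    thin-filament tension profile along the overlap region, steady-state
    calcium-tension curves, a Hill-equation comparator with three-parameter
    fitting, per-curve and shared-parameter model fitting to skinned-muscle
    style datasets, curve summary metrics (EC50, peak tension, apparent Hill
    coefficient), a synthetic dataset generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
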