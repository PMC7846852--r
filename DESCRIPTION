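Package: rvecv
Title: Right-Ventricular Extracellular Volume from Cardiac T1 Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying myocardial extracellular volume (ECV)
    of the thin-walled right ventricle from paired native and
    post-contrast T1 parametric maps. Implements the centerline
    "line of interest" (LOI) sampler (supercover traversal of the pixels
    crossed by an operator-drawn mid-wall polyline) alongside conventional
    planimetric region-of-interest (ROI) analysis, the hematocrit-scaled
    ECV formula, image-quality and wall-thickness grading with feasibility
    rules, a synthetic midventricular short-axis phantom with MOLLI
    inversion-recovery simulation, partial-volume mixing, noise and
    misregistration, and Bland-Altman / correlation agreement statistics
    for method comparison and observer-variability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
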