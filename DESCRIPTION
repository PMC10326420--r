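Package: scmorph
Title: Schlemm's Canal Morphometry and IOP-Response Analysis for Anterior-Segment OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric analysis of Schlemm's canal (SC) lumen segmentations from
    anterior-segment optical coherence tomography B-scan stacks. Extracts connected
    lumen components per cross-section, applies the largest-lumen / 20%-of-largest part
    selection rule, fits equal-second-moment ellipses in physical coordinates on
    anisotropic pixel grids, and derives per-cross-section width (sum of major axes),
    height (area-weighted minor axis), area, and per-eye volume over a fixed analyzed
    length. Provides normalization schemes (control-anchored relative volume, per-eye
    normalization to a reference intraocular-pressure offset), ordinary-least-squares
    estimation of morphometric response slopes versus IOP offset with t-based confidence
    intervals, ANCOVA-style slope-difference tests, and per-level group contrasts with
    Sidak adjustment. Includes a synthetic phantom generator producing binary SC mask
    stacks with exact analytic ground truth and a configurable linear deformation model,
    enabling closed-loop parameter-recovery validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
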