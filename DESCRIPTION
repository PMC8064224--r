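Package: retnorm
Title: Normative Retinal Layer Thickness Analysis for Mouse OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal normative analysis of retinal layer thickness from
    segmented mouse spectral-domain optical coherence tomography (SD-OCT)
    volumes. Converts per-interface depth surfaces (512 B-scans of 512 A-scans,
    1024 depth pixels over 1.4 mm) into per-layer micrometre thickness maps,
    standardizes eye orientation, applies per-pixel validity criteria, and
    aggregates maps into 3x3 blocks of 170x170 values with an inclusive 90%
    retention rule. Builds and queries normative databases (mean, sd, n per
    layer, age, eye and block), including packaged whole-area reference tables
    for C57BL6/129S wild-type and 3xTg-AD mice at one to four months of age.
    Provides cross-sectional Welch/Student t comparisons with 5/1/0.1%
    significance tiers, nasal-temporal asymmetry testing, repeated-measures
    ANOVA across the four monthly time points with Tukey-corrected pairwise
    contrasts, and per-eye normative deviation maps reporting signed z scores
    and two-sided p-values. A seeded synthetic-volume generator emulates the
    layered retinal geometry (nasal-temporal gradient, decline with distance
    to the optic disc, per-pixel noise, injectable invalid regions) so the
    whole pipeline is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    withr,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
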