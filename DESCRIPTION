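Package: gliogrowth
Title: Growth Detection in Low-Grade Gliomas from Longitudinal Tumor Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-assisted detection of growth in low-grade (WHO grade 2)
    gliomas from longitudinal FLAIR-derived tumor volumes. Computes volumes and
    bidimensional products from axial binary mask stacks, determines the
    post-resection baseline (first volume minimum after surgery), detects growth
    with an online penalized change-point method on the root-mean-square level
    that at each clinic visit uses only past measurements, classifies growth
    kinetics as linear or exponential by penalized curve fitting of normalized
    growth curves, and summarizes cohorts (time to growth, volume change at
    detection, Mann-Whitney-Wilcoxon comparisons against visual-comparison
    reads). Includes a synthetic-data generator producing volume trajectories
    and ellipsoid mask phantoms with the statistical structure the analysis
    assumes, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
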