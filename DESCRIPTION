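Package: artdose
Title: Dosimetric and Geometric Analysis of Online-Adaptive Head-and-Neck Radiotherapy
Version: 0.1.0
Authors@R:
    person("Maintainer", "artdose", email = "artdose@example.org", role = c("aut", "cre"))
Description: Tools to compare online-adaptive versus scheduled (image-guided)
    head-and-neck radiotherapy courses on a voxel grid: generalized equivalent
    uniform dose (gEUD) and dose-volume-histogram metric panels per fraction,
    Euclidean distance-transform margin operations (PTV expansion, stepwise
    CTV erosion), displacement-field dose accumulation per treatment phase with
    a minimum-adequate-margin criterion, rank-based statistics for inter- versus
    intrafractional anatomical landmark motion, and a fully seeded synthetic
    phantom cohort generator that stands in for clinical CBCT/plan data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
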