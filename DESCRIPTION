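Package: splenial
Title: Splenial Angle and Companion Radiological Indices of Ventriculomegaly
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring the splenial angle, an axial angular index of
    lateral ventriculomegaly read off directionally-encoded color fractional
    anisotropy (FA) maps, together with the two established reference indices
    (Evans' index and the callosal angle). Includes a diffusion tensor fitting
    and color-FA encoding pipeline, a fully automated splenial angle
    landmarking chain, parametric 3D digital phantoms with known ground-truth
    angles, synthetic cohort and follow-up generators calibrated to published
    group moments, and a statistical evaluation harness: intraclass
    correlation, pairwise Benjamini-Hochberg comparisons, ROC screening
    analysis with closest-to-top-left cutoffs, stepwise logistic prediction,
    and shunt-change testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
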