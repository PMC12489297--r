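Package: c4aci
Title: Apparent C4 Photosynthetic Capacity from A/Ci Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates apparent maximal PEP carboxylation activity (VpmaxA) and
    CO2-saturated assimilation (Amax) from C4 A/Ci gas-exchange curves using the
    enzyme-limited von Caemmerer model for the initial slope and a
    non-rectangular hyperbola for the full curve, propagating sampling variances
    from the fits. Consolidates replicate curves into experimental groups,
    applies point-count and limitation-consistency quality filters, and analyses
    the resulting estimates with a multilevel mixed-effects meta-regression with
    known sampling variances (REML), including Wald inference,
    marginal/conditional R-squared, model-predicted marginal means, prediction
    surfaces, standardized major axis slopes by temperature bin, and a
    logarithmic Amax-VpmaxA fit. A synthetic-data generator reproduces the
    grouped, multi-study structure of compiled gas-exchange datasets so every
    stage can be checked against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), metafor, jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
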