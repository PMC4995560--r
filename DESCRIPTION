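Package: stemallometry
Title: Covariation of Tree Height, Diameter and Stem Volume Allometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intra-specific analysis of tree height (H), diameter at
    breast height (D) and stem volume (V) power-law allometry. Fits site-level
    log10-log10 scaling relationships by reduced major axis (RMA) and ordinary
    least squares (OLS) regression, tests slope heterogeneity across sites,
    estimates the shared covariation parameter phi linking the three
    volume-scaling exponents (y' = phi/(2+x), z' = phi/(1+2/x), y' = (phi-z')/2),
    models the linear coupling between normalization constants and exponents,
    and calibrates a nondestructive stem-volume predictor that maps a site's
    H-vs-D exponent and a tree's diameter to predicted stem volume, evaluated by
    mean absolute percentage error. Includes sectional (truncated-cone) stem
    volume computation from disc measurements and a synthetic multi-site forest
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
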