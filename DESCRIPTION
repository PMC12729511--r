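Package: iqzone
Title: Integrated Quality Zoning for Medicinal Plants from Ecological and
    Phytochemical Suitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates integrated quality regions for medicinal plants by
    fusing two suitability surfaces: an ecological one from a maximum-entropy
    presence-background species distribution model (linear, quadratic and
    hinge features, L1 regularization, cloglog output, cross-validated AUC,
    jackknife variable importance, response curves) and a quality one from
    ordinary co-kriging of leaf compound concentrations under a linear model
    of coregionalization. Includes spatial rarefaction of occurrence records,
    correlation and variance-inflation-factor predictor pruning, Spearman
    screening of compound-environment associations, habitat reclassification
    with area ledgers and centroid-migration tracking, Fisher-Jenks natural
    breaks classification, raster I/O (ESRI ASCII and single-band GeoTIFF),
    and a synthetic-landscape generator with known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
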