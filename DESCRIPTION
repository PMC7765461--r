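Package: pasturespec
Title: Hyperspectral Canopy Retrieval from Multispectral Bands and
    Pasture Biomass Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs narrowband top-of-canopy reflectance (550-790 nm)
    from four multispectral band values with a piecewise linear-logistic
    red-edge model, derives continuum-removal band-depth features from the
    reconstruction, and estimates pasture biomass (kg DM/ha) with tuned
    random-forest regression under both plain and leave-one-location-out
    spatial cross-validation.  A synthetic grass-canopy spectral generator
    with known ground truth makes every stage of the workflow testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
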