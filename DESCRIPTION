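Package: CropSuit
Title: AHP Weighted-Overlay Crop Suitability Mapping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-criteria crop-suitability analysis on co-registered
    environmental raster layers. Derives criterion and subclass weights from
    Saaty pairwise-comparison matrices with a consistency-ratio gate,
    reclassifies terrain, soil and climate layers through packaged per-crop
    classification schemes (rice and coconut), combines them by weighted
    overlay into a suitability index, classifies the index into four
    equal-interval suitability classes, masks non-cropland land cover, and
    tabulates class areas. Includes climate-layer preparation (monthly
    climatology, growing-season aggregation, inverse-distance-weighted
    downscaling with cross-validated power selection), presence/absence
    AUROC validation, and a seeded synthetic coastal-landscape generator for
    fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
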