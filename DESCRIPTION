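Package: aeropheno
Title: UAV Multispectral Phenotyping of Low-Nitrogen Stress in Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of low-altitude multispectral imagery over
    nitrogen-response field trials: color-filter-array demosaicing,
    empirical-line radiometric calibration, position-based mosaicking,
    per-row region-of-interest extraction of vegetation reflectance,
    vegetation and stress indices (NDVI, a nitrogen stress index,
    hue-threshold green fractions and a crop senescence index), spatial
    field-variability statistics, broken-stick nitrogen-response regression
    and stratified correlation analysis.  Includes a synthetic field-trial
    generator that renders multispectral frames and plot-level RGB canopy
    images with known ground truth, so the full pipeline is testable without
    flight data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
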