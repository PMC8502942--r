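Package: thzvol
Title: Terahertz Transmission Imaging Tumor Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for fiber-scanned terahertz (THz) transmission
    imaging of subcutaneous tumors. Simulates noisy transmitted-power rasters
    of a skin/fat/tumor tissue phantom, inverts them to absorption-coefficient
    maps via the Beer-Lambert law, calibrates out the uniform skin attenuation
    background, segments cancer pixels by absorption-coefficient bands, and
    converts the regional absorption change into cancer-cell density and total
    tumor volume through an absorption-cross-section model. Includes
    tissue-spectroscopy aggregation over 108-143 GHz, detection-limit and
    penetration-depth calculators, tidy() and glance() methods for results,
    and ggplot2 visualisations of absorbance and label maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    scales,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
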