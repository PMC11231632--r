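Package: phenolys
Title: Whole-Plant Drought Phenotyping from Gravimetric Lysimeter Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-plant water-relations phenotyping on
    gravimetric (load-cell) lysimeter platforms. Converts high-frequency pot
    weight series into daily transpiration, whole-plant transpiration rate,
    canopy stomatal conductance, calculated plant weight and soil water
    content; estimates the critical soil-water-content breakpoint (theta-crit)
    and maximal transpiration by broken-stick regression; derives vigor,
    resilience, recovery and water-use-efficiency metrics; and classifies
    drought-response strategies (dynamic, isohydric, anisohydric) with
    Tukey HSD compact-letter summaries. Includes a water-balance simulator of
    the soil-plant-atmosphere system with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
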