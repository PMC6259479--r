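Package: phytoscreen
Title: Heavy-Metal Biomonitoring Indices for Soil-Plant Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for heavy-metal biomonitoring studies that pair
    polluted-site soil and plant-tissue concentration data with a control
    baseline. Computes contamination factors and the pollution load index
    (geometric mean of contamination factors), classifies them on the
    Lacatusu contamination/pollution interval scheme, screens concentrations
    against WHO/DPR/USEPA regulatory limits, and derives plant accumulation
    metrics (aerial portion, translocation factor, plant/soil concentration
    ratio). Includes paired t-test and Pearson correlation screening between
    soil and tissue parameters, a seeded lognormal synthetic-data generator
    with closed-form ground truth for end-to-end validation, and a config
    driven pipeline runner that emits the standard report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    purrr,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
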