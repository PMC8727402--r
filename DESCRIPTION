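Package: chickcold
Title: Cold-Temperature Yield Thresholds for Chickpea from Thermal-Time Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the effect of cold temperature during the
    reproductive period on chickpea (Cicer arietinum) yield. Implements a
    soil-water-modified thermal-time phenology engine (thermal time scaled by
    fractional available soil water above an activation boundary), post-flowering
    frost-event yield penalties, goodness-of-fit statistics (RMSD with the N-1
    divisor, Willmott's index of agreement, R squared), and a grid-search
    procedure that detects a location-specific cold-temperature threshold by
    regressing frost-affected yield on the percentage of cold reproductive-period
    days and reproductive-period rainfall. A synthetic-data module generates
    SILO-style daily weather, a bucket soil-water balance, and annual yields with
    a known implanted cold effect, so the whole pipeline can be exercised and its
    parameter recovery verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
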