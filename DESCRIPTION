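Package: micmon
Title: Calibrator-Based Absolute Quantification and Dynamics Analysis for
    Drinking-Water Microbiome Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts replicate-level 16S rRNA gene OTU read counts into
    absolute gene-copy concentrations using a spiked internal calibrator,
    subtracts reagent contamination estimated from negative extraction
    controls processed in triplicate, and analyses the spatial and temporal
    dynamics of a drinking-water distribution system: per-location medians,
    dominance classification, consecutive-location fold changes, Spearman
    trend tests, and anomaly detection. Includes a synthetic-data module
    that simulates monitoring campaigns with known ground truth (kill-off,
    regrowth, seasonal modulation, reagent contamination, multinomial read
    sampling) and a concordance module comparing total-biomass series
    across measurement methods.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
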