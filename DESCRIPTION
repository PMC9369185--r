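Package: tetraspot
Title: Single-Vesicle Tetraspanin Colocalization Analysis for Immunocapture Chip Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single extracellular-vesicle (sEV)
    phenotyping data from antibody-microarray immunocapture platforms with
    three-colour fluorescence detection and interferometric sizing (SP-IRIS,
    ExoView-style chips). Builds per-capture-spot tetraspanin (CD9/CD63/CD81)
    colocalization tables, capture-spot particle distributions and size
    summaries, and tests the observed marker co-occurrence against a
    conditional-independence random-assignment null model, reporting fold
    over- or under-representation of each colocalization category. Includes a
    seeded forward simulator of chip experiments so the whole analysis can be
    exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
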