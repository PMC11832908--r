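Package: petsr
Title: Local Extinction Potential from Multi-Source Species Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating and cleaning species occurrence records from
    heterogeneous sources (faunistic literature and collections, citizen
    science, structured expert sampling) and for estimating sightings-based
    local extinction potential. Implements the PETS statistic (Potential
    Extinction upon Time Series) - the fraction of a species' known regional
    history during which it has gone unobserved - at species and community
    level, with source-exclusion sensitivity analysis, species-by-year
    persistence/absence timelines, fixed-resolution (UTM) grid occupancy by
    source, and yearly record and richness aggregation tables. A seeded
    synthetic multi-source recording generator with known ground truth (true
    extinction years, effort regimes, detectabilities) makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    geosphere,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
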