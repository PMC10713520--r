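Package: geobib
Title: Geographic Disparity Analysis for Bibliometric Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit geographic representation in scholarly publishing
    from publication-metadata exports. Parses Web of Science style
    tab-delimited records, geolocates corresponding-author addresses against
    an offline gazetteer, aggregates publication and citation counts by
    country or city, fits the log-log publication-citation relation and
    derives per-unit publication excess and deficit, computes the Domestic
    Self-Citation Index on a citing-country by cited-country matrix, tests
    journal-country composition, fits temporal trends, and clusters national
    citation fingerprints. Includes a synthetic-data generator with a
    controllable domestic-citation preference so the full pipeline is
    testable without any proprietary download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
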