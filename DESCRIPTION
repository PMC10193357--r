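Package: mobstyle
Title: Latent Activity Behaviors and Lifestyles from Urban Mobility Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers latent activity behaviors from venue-visit mobility
    records by Kullback-Leibler non-negative matrix factorization, selects the
    factorization rank by restart stability and bi-cross-validation, and
    derives per-user lifestyle statistics: normalized behavior-weight entropy,
    experienced income integration, income-quartile exposure shares, and place
    exploration. Fits city fixed-effects regressions linking behavior weights
    and area demographics to social, transportation, and health outcomes, and
    ships a synthetic mobility generator that emulates the statistical
    structure of proprietary ping/venue data so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
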