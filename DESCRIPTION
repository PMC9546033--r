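Package: refugium
Title: Presence-Background Distribution Models and Climate Refugia for
    Alpine Birds
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits presence-background maximum-entropy species distribution
    models with linear and quadratic features, L1 regularization and
    cloglog output, selects them by a presence/background-only AICc with a
    greedy tuning loop, and evaluates them with spatial-block
    (checkerboard) cross-validation, AUC, TSS and omission rates.
    Projections under alternative future climate conditions are binarized
    at the 10th-percentile training threshold and classified into in-situ
    and ex-situ climate refugia, with a protected-area gap analysis
    overall and per country.  A seeded synthetic alpine landscape
    generator (terrain, lapse-rate climate, fractional land cover,
    protected areas, noisy citizen-science style occurrence records)
    makes the whole pipeline runnable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
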