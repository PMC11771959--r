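Package: aeroforage
Title: Central-Place Foraging of Aerial Insectivores Against Radar-Measured
    Insect Traffic
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking reverse-GPS (ATLAS) tracking of
    colony-breeding aerial insectivores to vertical-beam radar measurements
    of aerial insect abundance. Implements fix-level track filtering (speed,
    localization-error fence, base-station count, jump, daylight and
    minimum-tags rules) with full attrition accounting, per-day
    central-place foraging metrics (colony distances, daily route, colony
    visits detected from reception gaps, foraging and roosting durations,
    arrival/departure timing relative to sunset/sunrise, inter-individual
    distance), insect movement traffic rate (MoTR) from radar echoes,
    Gamma/Gaussian GLM inference with small-sample AICc model averaging,
    and a seeded synthetic-data generator with a ground-truth record so the
    whole chain is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fitdistrplus,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
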