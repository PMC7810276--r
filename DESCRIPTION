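Package: natremia
Title: Predicting the Plasma Sodium Response to Crystalloid Fluid Therapy in SIADH
Version: 0.1.0
Authors@R:
    person("natremia", "maintainers", email = "natremia@example.org",
           role = c("aut", "cre"))
Description: Closed-form prediction of the change in plasma sodium
    concentration after crystalloid (NaCl) intravenous fluid therapy in
    patients with the syndrome of inappropriate antidiuretic hormone
    secretion (SIADH). Implements the electrolyte-free-water-balance
    (Voets) equation, the classic Adrogue-Madias redistribution equation
    and its volume-generalized form, total-body-water estimation,
    cohort-level validation statistics (Pearson correlation, t-based
    p-values, Fisher-z sample-size calculation), a bundled 15-measurement
    SIADH validation cohort, a seeded synthetic-cohort generator, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
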