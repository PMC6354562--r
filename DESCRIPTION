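Package: anccover
Title: Antenatal Care Effective-Coverage Cascades and Lives-Saved Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts longitudinal antenatal care records into the effective-coverage
    and health-status indicators used by deterministic lives-saved policy models,
    following clinical screening-and-referral cascades for gestational diabetes,
    hypertensive disorders and pre-eclampsia, plus tetanus vaccination, iron-folate
    supplementation, anemia and low body-mass-index indicators. Includes a seeded
    synthetic cohort generator emulating paper-based and electronic-registry record
    dialects, estimators for routine-report aggregates and indirect survey-based
    coverage, a simplified multiplicative residual-risk projection engine comparing a
    steady-state scenario against a public-sector scale-up, and per-intervention
    attribution of deaths and anemia cases averted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
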