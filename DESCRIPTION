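Package: carelex
Title: Quantitative Linguistics of Clinical Practice Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Encodes paired patient-derangement / practitioner-intervention
    observations from mechanical-ventilation sessions and dialysis
    anemia-management records as symbolic "words", characterizes their
    rank-frequency statistics with log-log power-law (Zipf) fits, and
    compares observed intervention-pattern-length and solution-length
    distributions against intermittent-silence ("monkey typing") and
    random-text null models.  Includes seeded synthetic-data generators
    for both clinical domains so every stage of the pipeline can be
    exercised and calibrated without access to clinical logs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
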