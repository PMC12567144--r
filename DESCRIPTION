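Package: lungdose
Title: PBPK-Guided Translation of Oral Anti-Tuberculosis Doses to Inhaled Lung Doses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body perfusion-limited physiologically based pharmacokinetic
    (PBPK) simulation of oral rifampicin, ethambutol and moxifloxacin, with
    non-compartmental analysis and a prediction-error validation gate, used to
    translate clinical oral doses into inhaled lung doses and salt-aware
    fixed-dose-combination molar ratios for dry powder inhaler development.
    Also provides the deterministic formulation analytics used to judge the
    resulting powders (cascade-impactor emitted and fine particle fractions,
    content uniformity, particle-size distribution summaries, and dissolution
    with sampling-volume correction) together with synthetic-data generators
    that stand in for the laboratory instruments so every stage is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
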