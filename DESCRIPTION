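Package: empirx
Title: Guideline-Based Clinical Decision Support for Empirical Antibiotic Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable engine for guideline-based empirical antibiotic
    prescribing and its stewardship evaluation. Encodes diagnosis flowcharts
    and per-drug renal dosing rules in a declarative, validatable knowledge
    base; traverses pathways for a patient with automatic data binding
    (pregnancy, IgE allergy, neutropenia), an obligatory antibiogram-review
    gate, susceptibility- and allergy-driven deviation from first-choice
    regimens, and eGFR/weight-refined dose selection. Includes clinical
    calculators (CURB-65, Devine ideal body weight, BMI), prophylaxis and
    adherence classifiers, proportional stratified sampling with binomial
    confidence intervals for CDSS-eligibility extrapolation, and a seeded
    synthetic cohort generator so every component is testable without
    hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
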