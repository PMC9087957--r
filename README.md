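# empirx

Guideline-based clinical decision support for empirical antibiotic therapy,
with the stewardship evaluation to go with it.

`empirx` is for researchers and stewardship teams who want a *testable*
rule-based CDSS engine: the guideline content lives in a declarative,
machine-checkable knowledge base (YAML/JSON flowcharts plus per-drug renal
dose tables), the engine that binds patient data to those flowcharts is a
deterministic library function, and the evaluation of such a system on a
hospital cohort — who could have used it, who did, and whether its advice
was followed — is reproducible code instead of a chart-review spreadsheet.

## What it implements

**Advisor engine.** For a working diagnosis, the engine traverses the
diagnosis flowchart: questions are auto-answered from the patient record
where a data binding exists and the value is present and fresh (pregnancy,
IgE-mediated penicillin allergy, neutropenia), otherwise asked; an
obligatory antibiogram-review gate attaches the culture history of the
previous 6 months (183 days) before the pathway may proceed. At the
terminal node the first-choice regimen is checked against the windowed
antibiogram history and recorded allergies — a resistant (R) result or a
class-matching allergy triggers deviation to the first conflict-free
declared alternative, else referral to the infectious disease specialist.
Each drug's dose is then selected from half-open eGFR bands
(mL/min/1.73 m²; eGFR observations expire after strictly one week), with
gentamicin dosed per kg Devine ideal body weight

  IBW = 50 kg (men; 45.5 kg women) + 0.9055 × (height_cm − 152.4).

Clinical calculators: CURB-65 (score = #{confusion, urea > 7 mmol/L,
RR ≥ 30/min, SBP < 90 or DBP ≤ 60 mmHg, age ≥ 65}; risk low/moderate/high
at 0–1/2/≥3) and BMI.

**Stewardship evaluation.** The cohort filter keeps adults admitted > 1 day
with ≥ 1 systemic antibacterial (ATC `J01…`) that is not solely
prophylactic. Prophylaxis is classified by fixed rules (course < 48 h,
cotrimoxazole 480 mg, perioperative cefazolin without another indication,
SDD/neutropenia/COPD protocols, pheneticillin ≤ 2 years post-splenectomy).
Eligibility for the CDSS is estimated from a proportional stratified random
sample (largest-remainder allocation over wards) with a Wald interval
p̂ ± z·√(p̂(1−p̂)/n), extrapolated as ⌊N · round(p̂, 3)⌋. Adherence of
prescriptions started within 24 h of an advice is classified
complete / partial / none (partial: a proper subset of advised drugs, or a
different route or dosage regimen).

**Synthetic cohorts.** A seeded generator produces cohorts, CDSS sessions
and ground truth emulating the evaluation's statistical structure (ward
strata, eligible-diagnosis prevalence, adherence mixture realized against
the engine's own advice, prophylaxis-only patients, resistant prior
cultures, test sessions), so everything is testable without hospital data.

## Worked example

```r
library(empirx)

kb <- load_example_kb()                    # 7 diagnoses, validated
validate_kb(kb)
#> Knowledge base is valid (0 violations)

pt <- new_patient("P1", "1955-06-01", "female", "internal_medicine",
                  "2017-01-10 08:00:00", "2017-01-20 08:00:00",
                  weight_kg = 70, height_cm = 165, pregnant = FALSE,
                  observations = data.frame(kind = "egfr", value = 80,
                    observed_at = as.POSIXct("2017-01-11 06:00:00", tz = "UTC")))

s <- start_session(kb, pt, "pneumonia", "2017-01-11 12:00:00")
s <- submit_answer(s, "hap")     # hospital-acquired
s <- submit_answer(s, "no")      # no IgE beta-lactam allergy
s <- acknowledge_gate(s)         # obligatory antibiogram review
generate_advice(s)
#> Antibiotic advice (pneumonia):
#>   piperacillin-tazobactam iv 4000 mg every 6 h
#>   duration: 5-7 days
```

The dose came from the ≥ 50 mL/min eGFR band; with eGFR 35 the same call
prints `every 8 h`, and with no eGFR observation in the last week the dose
field says `consult specialist (no valid eGFR within 1 week)`.

Evaluating a (here synthetic) cohort:

```r
g <- generate_cohort(cohort_config(n_patients = 3349, seed = 1))
evaluate(g$cohort, g$sessions, sample_n = 248, seed = 2)
#> CDSS stewardship evaluation
#>   evaluable cohort:            3020 patients
#>   stratified sample:           103 eligible of 248 = 41.5% (95% CI 35.4-47.7)
#>   extrapolated eligible:       1253 patients
#>   CDSS sessions:               183 (14 test) -> usage 13.4%
#>   real uses:                   169 (152 advice, 17 consult)
#>   followed: 86 complete + 25 partial of 169 = 65.6% (not followed: 58)
#>   ...
```

A thin command-line front end ships in `inst/cli/empirx.R`
(`validate-kb`, `advise`, `simulate`, `evaluate`).

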