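---
title: "A testable engine for guideline-based empirical antibiotic advice and its stewardship evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A testable engine for guideline-based empirical antibiotic advice and its stewardship evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empirx)
```

## The problem

Empirical antibiotic therapy — choosing an antibiotic before organism and
susceptibility are known — is where most guideline deviations happen, and
rule-based clinical decision support systems (CDSS) are a standard
stewardship response: link the patient record to a knowledge base of
guideline flowcharts and emit a patient-specific regimen. Such systems are
usually described as screenshots and prose. `empirx` turns the two halves
into code with testable contracts: (1) an advisor engine over a
declarative, validatable knowledge base, and (2) the stewardship
evaluation that asks, for a hospital cohort, how many patients *could*
have used the system, how many *did*, and whether its advice was followed.

This vignette is the package's own account of the model: what is computed,
which parameters matter, what the synthetic data emulate, and where the
edges are.

## The knowledge base and its validator

A knowledge base holds one flowchart per working diagnosis (the example
knowledge base covers sepsis, pneumonia, urinary tract infection, fever of
unknown origin with suspected bacterial infection, meningitis, secondary
peritonitis and liver abscess) plus one dose rule table per drug. The file
schema (YAML canonical, JSON equivalent; see
`inst/extdata/kb-schema.md`) is the normative artifact — flowchart figures
are renderings of it, not the other way round.

Design choices that were genuinely open:

* **Flowcharts are rooted DAGs, not trees.** Different answers may
  converge on the same downstream node (in the example pneumonia pathway,
  the no-allergy branches of hospital-acquired and high-risk
  community-acquired pneumonia share one gate-and-advice chain). Cycles are
  rejected by the validator.
* **Three node kinds suffice.** Questions (with optional data bindings),
  an antibiogram-review *gate* with exactly one successor — the machine
  form of "the physician is obliged to review the culture history before
  proceeding" — and terminal advice nodes that carry either a regimen with
  ranked alternatives or a referral to the infectious disease specialist.
* **Half-open eGFR bands.** Dose table rows are `[lo, hi)` in
  mL/min/1.73 m², so band edges are unambiguous: eGFR 50 takes the upper
  band, 30 the `[30, 50)` band. Bands must jointly cover `[0, Inf)` with
  no gaps or overlaps; the example tables use `>= 50`, `[30, 50)`,
  `[10, 30)`, `< 10`. A row may be an explicit *consult* row (no dose) —
  this is how a drug contraindicated in renal impairment (nitrofurantoin
  below 50) keeps full band coverage while routing to specialist dosing.
* **Validation is data, not exceptions.** `validate_kb()` returns every
  violation at once (dangling references, cycles, unreachable nodes, paths
  not ending in advice, questions with fewer than two distinct answers,
  advised drugs without a dose table, band gaps/overlaps). The motivating
  bug class — a pathway that reaches its end screen without generating an
  advice — is exactly a reachable non-advice sink. The example knowledge
  base is built so that *any* deletion of a node or answer edge trips at
  least one rule, which the test suite verifies over hundreds of random
  mutations.

The example knowledge base is **illustrative, not clinical**: structure and
drug choices follow the published description (piperacillin-tazobactam as
first choice for hospital-acquired and severe community-acquired pneumonia,
nitrofurantoin for uncomplicated cystitis, gentamicin dosed on ideal body
weight, an IgE-allergy question and an antibiogram gate in every pathway),
but thresholds and doses are placeholders where the source guideline is not
part of this artifact.

## The advisor engine

`start_session()` places a session at the pathway root;
`submit_answer()` / `acknowledge_gate()` advance it; `generate_advice()`
composes the outcome at the terminal node. Three rules govern traversal:

* **Auto-answering.** A question with a data binding is answered from the
  record when the value is present and trustworthy, otherwise surfaced to
  the physician: men are never asked about pregnancy, women with unknown
  status always are (no age cutoff — the original design debate on when to
  stop asking is resolved here by always asking); a *recorded* IgE-mediated
  penicillin/beta-lactam allergy auto-answers "yes", but an empty allergy
  list never auto-answers "no", because absence of a record is not absence
  of an allergy; neutropenia binds to the most recent absolute neutrophil
  count (threshold 0.5 × 10⁹/L). A manual `override_answer()` can rewind
  and overwrite any answer, automatic ones included, keeping the
  superseded answers in the session trail.
* **Freshness windows.** Culture results are presented and used for
  deviation only from the previous 6 months, fixed at 183 days; an eGFR
  auto-feeds dosing only if determined strictly less than 1 week
  (7 × 24 h) before the consultation. Fixed integer windows make the
  binding rules exactly testable; both are half-open on the old side
  (an observation exactly 7 days old is stale).
* **Deviation then dosing.** At the terminal regimen, a resistant (`R`)
  result for any first-choice drug in the windowed antibiogram history, or
  a recorded allergy matching a drug's class, triggers deviation: the
  declared alternatives are scanned in order and the first one free of
  both conflicts is chosen (first fit; the source system's ranking
  behaviour beyond first fit is undocumented, so nothing fancier is
  attempted). Intermediate (`I`) results deviate only when
  `treat_intermediate_as_resistant = TRUE` (default off — the published
  rule is deviation "if necessary", and `I` is commonly exposure-dependent).
  If every alternative conflicts, the advice becomes a specialist referral.
  Dose selection then resolves each drug's eGFR band, skips
  pregnancy-disallowed rows (falling through to consult), and converts
  per-kg doses via the Devine ideal body weight (floored at the base value
  below 152.4 cm) or the recorded actual weight, rounding the total to the
  nearest mg.

The engine is deterministic: identical knowledge base, patient, answers
and timestamp give identical advice. Its ground truth is
`enumerate_paths()`, an exhaustive DFS over the pathway; the test suite
replays *every* enumerated answer sequence (21 paths across the seven
example pathways) through the engine and checks that each reproduces its
terminal, and that no generated advice ever contains a drug outside the
terminal node's regimen and declared alternatives.

CURB-65 uses the standard published criteria (confusion, urea > 7 mmol/L,
respiratory rate ≥ 30/min, systolic < 90 or diastolic ≤ 60 mmHg,
age ≥ 65) with risk low at 0–1, moderate at 2, high at ≥ 3 — the mapping
the severity split in the pneumonia pathway expects.

## The stewardship evaluation

The evaluation pipeline fixes every quantity the chart review left
informal:

* **Cohort filter**: adults (≥ 18 at admission), admission strictly longer
  than 24 h, at least one ATC `J01` prescription, at least one of them
  non-prophylactic.
* **Prophylaxis rules**, applied in fixed order, first match wins: course
  duration < 48 h; cotrimoxazole at 480 mg (after mg/g normalization);
  cefazolin started pre-, intra- or post-operatively without another clear
  indication — that indication is an explicit boolean input
  (`other_indication`), never inferred, because the original assessment
  was manual; the protocol tags SDD, neutropenia, COPD; pheneticillin
  started within 2 years (fixed at 730 days) after splenectomy. The test
  suite checks the classifier against an independent all-rules oracle on
  10,000 randomized prescriptions.
* **Adherence** of prescriptions to an advice is classified over a 24-hour
  window after the advice (the review had no stated window; a fixed one
  makes the classifier deterministic): *complete* = every advised drug
  prescribed with matching route and dosage regimen (dose after unit
  normalization, and interval when the advice specifies one — a missing
  prescription interval counts as a mismatch); *partial* = some advised
  drug prescribed but a proper subset, or with different route or regimen;
  *none* = no advised drug. Ambiguity is surfaced in the per-drug `detail`
  table rather than resolved by guessing; the categories partition by
  construction.
* **Eligibility** is estimated from a proportional stratified random
  sample over wards (largest-remainder allocation summing exactly to the
  sample size, ties broken by stratum name, allocations capped at stratum
  size) with a **Wald** interval, clipped to [0, 100]. Wald is the
  simplest method consistent with the symmetric interval the evaluation
  design reports; the sample-coverage test tolerates its mild
  undercoverage (≥ 93% observed over 500 seeded replicates at n = 248,
  p = 0.40). The eligible count is extrapolated as
  `floor(N * round(k/n, 3))` — the proportion is rounded to three decimals
  *before* scaling, which is the arithmetic that makes 100/248 of 3349
  patients exactly 1349.
* **Rates** are printed truncated (not rounded) to one decimal:
  usage = 100 × (sessions − test sessions) / extrapolated eligible;
  followed = 100 × (complete + partial) / real uses. The adherence
  denominator is *all* real uses including consult advices, which
  therefore count towards "not followed" — that is the arithmetic behind a
  followed rate like 114/169 = 67.4%.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the evaluation
assumes, at the study's own scale and with its reported rates as defaults:
3349-patient cohorts, eligible-diagnosis prevalence 0.403, session rate
0.125 among eligible patients, test sessions ~8% of all sessions
(15/184), adherence mixture 0.55/0.15/0.30, prophylaxis-only rate 0.10 and
prior-culture resistance rate 0.10 (the last two are not reported
quantities; they are set to values a stewardship dataset of this kind
plausibly shows and are freely configurable).

Choices worth knowing:

* **Eligibility is Bernoulli over all patients, independent of
  prophylaxis-only status.** This keeps the overall eligible count
  binomial *and* the eligible fraction of the filtered cohort equal to the
  configured prevalence — both are tested. Diagnoses are drawn with
  pneumonia and urinary tract infection most frequent, mirroring the
  reported consultation pattern.
* **Adherence is realized against the engine's own advice.** A session
  replays a random path through the example knowledge base (auto-answers
  included), and the intended category is then constructed exactly:
  complete copies every advised drug, dose, route and interval; partial
  drops one drug of a multi-drug regimen or flips the route (both
  sub-modes recorded in the ground truth); none prescribes a systemic
  antibacterial outside the advised set. Sessions whose advice ends in a
  consult (or whose dose decisions require a consult, e.g. quinolones in
  pregnancy) are not realizable as adherence cases; their ground-truth
  category is `NA` and the patient receives ordinary empirical therapy so
  the cohort filter still includes them.
* **A single seeded RNG stream with a fixed, vectorized draw order.**
  Patient-level attributes are drawn as whole vectors before any
  per-patient work, so output is byte-identical across runs of the same
  configuration and insertion order cannot perturb downstream draws.
* **What is *not* emulated:** microbiology beyond one illustrative
  resistant E. coli antibiogram; correlated comorbidity; incomplete or
  erroneous records (every generated patient has a fresh eGFR when a
  session needs one); physicians answering questions *wrongly*, which the
  original study identified as a major source of non-adherence. Passing
  tests on synthetic cohorts therefore demonstrate that the pipeline's
  arithmetic and classifiers are correct under the configured mixture —
  not that a real hospital's adherence behaves like the mixture.

Problem sizes used by the test suite — chosen as the smallest that
exercise the claims at their natural scale — are: the full 3349-patient
cohort for the binomial eligibility check, ~2250 patients (~2000 realized
advices) for adherence-mixture recovery within 3 binomial standard errors,
500 seeded replicates of 400-patient cohorts for CI coverage, 10,000
random prescriptions for the prophylaxis oracle, and ≥ 120 random
knowledge-base mutations.

## Known limitations

* The example knowledge base is a structural stand-in; encoding a real
  national guideline (and keeping it current) is deliberately out of
  scope, as are the web UI and hospital-information-system integration of
  the original system.
* eGFR is consumed as an extracted observation; computing it from
  creatinine is out of scope.
* The published 95% CI of the eligibility proportion is symmetric ±6.0,
  which matches no standard interval exactly (Wald gives ±6.1); the
  package documents and tests its own Wald construction and does not claim
  to reproduce those printed bounds.
* Allergy matching is class-based over a small illustrative drug-class
  map; cross-reactivity nuance (e.g. selective side-chain reactivity) is
  not modelled.
* Adherence classification sees only prescription data; dose adjustments
  recorded as free text, tapering schedules, or drugs restarted after the
  24-hour window are invisible to it.
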