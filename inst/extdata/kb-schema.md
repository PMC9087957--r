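# Knowledge-base file schema

A knowledge base is a YAML (canonical) or JSON document; the two are
equivalent. `example-kb.yaml` in this directory is a complete, valid
instance. The schema — not any rendered flowchart — is normative for this
package.

## Top level

```yaml
version: "1.0"          # free-form text
diagnoses:              # named mapping: diagnosis name -> pathway
  <diagnosis>: { root: <node id>, nodes: { <node id>: <node>, ... } }
dose_rules:             # named mapping: drug id -> dose rule table
  <drug>: { rows: [ <row>, ... ], fallback: consult }
```

## Pathways

A pathway is a rooted directed acyclic graph. Answers may converge (two
questions may lead to the same node), but every path from the root must
terminate in an advice node. `validate_kb()` enforces: acyclicity,
reachability of every node from the root, termination in advice, at least
two distinct answers per question, one successor per gate, a dose table for
every advised drug, and eGFR band coverage (below).

### Node kinds

**question** — asked of the physician, or auto-answered from the patient
record when `data_binding` is set and the bound value is present and fresh:

```yaml
q_pregnant:
  kind: question
  prompt: "Is the patient pregnant?"
  data_binding: pregnant        # optional; see bindings below
  edges: { yes: gate_a, no: gate_b }   # answer value -> next node id
```

Supported bindings: `pregnant` (men auto-answer "no"; women with unknown
status are always asked), `allergy_penicillin_ige` (auto-answers "yes" on a
recorded IgE-mediated penicillin/beta-lactam allergy; never auto-answers
"no" — records may be incomplete), `neutropenic` (most recent absolute
neutrophil count < 0.5 x 1e9/L).

**gate** — the obligatory antibiogram review. Traversal stops until the
gate is acknowledged; acknowledging attaches the culture results of the
previous `window_days` days (183 = 6 months) to the session:

```yaml
gate_a: { kind: gate, gate_kind: antibiogram_review, window_days: 183, next: adv_a }
```

**advice** — a terminal node: either a regimen or a referral to the
infectious disease specialist (`consult: true`).

```yaml
adv_a:
  kind: advice
  regimen:
    drugs: [ { drug: ceftriaxone, route: iv }, { drug: gentamicin, route: iv } ]
    duration_days: 7            # scalar or [lo, hi]
    alternatives:               # ordered; first conflict-free one is chosen
      - drugs: [ { drug: ciprofloxacin, route: iv } ]
        duration_days: 7
```

`alternatives` is the deviation list for resistance (an `R` result for a
first-choice drug in the windowed culture history) or a matching recorded
allergy; route is `iv` or `oral`.

## Dose rule tables

Rows are half-open eGFR bands `[egfr_min, egfr_max)` in mL/min/1.73 m2 that
must jointly cover `[0, Inf)` without gaps or overlaps. A row either
carries a dose or is an explicit consult row:

```yaml
gentamicin:
  fallback: consult
  rows:
    - { egfr_min: 50, egfr_max: .inf, dose: 5, unit: mg/kg,
        interval_hours: 24, weight_basis: ideal, pregnancy_allowed: false }
    - { egfr_min: 30, egfr_max: 50, dose: 5, unit: mg/kg,
        interval_hours: 36, weight_basis: ideal, pregnancy_allowed: false }
    - { egfr_min: 10, egfr_max: 30, consult: true, pregnancy_allowed: false }
    - { egfr_min: 0,  egfr_max: 10, consult: true, pregnancy_allowed: false }
```

`weight_basis` is `none` (default), `actual`, or `ideal` (Devine formula;
the per-kg dose is multiplied by the computed weight and rounded to the
nearest mg). `pregnancy_allowed: false` rows are skipped for pregnant
patients, which routes to the consult fallback. A single row
`{ egfr_min: 0, egfr_max: .inf, ... }` declares a renally independent drug;
for any other table an absent or stale eGFR (older than 1 week) yields a
consult dose decision.
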