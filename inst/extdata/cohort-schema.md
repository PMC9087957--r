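# Cohort extract schema

Canonical form: JSON lines — one patient object per line (`cohort.jsonl`).
A CSV bundle directory is accepted as an alternative. All timestamps are
UTC, ISO-8601 (`YYYY-MM-DDTHH:MM:SSZ`); dates are `YYYY-MM-DD`. Unknown
fields are rejected on read.

## Patient object (JSON lines)

```json
{
  "patient_id": "P00001",
  "birth_date": "1952-03-14",
  "sex": "female",                  // male | female
  "ward": "internal_medicine",
  "admission_start": "2017-01-10T08:00:00Z",
  "admission_end":   "2017-01-20T08:00:00Z",
  "weight_kg": 70.5,                // nullable
  "height_cm": 165.0,               // nullable
  "pregnant": false,                // true | false | null (unknown)
  "diagnoses": ["pneumonia"],       // ground-truth labels, evaluation only
  "allergies": [ { "drug_class": "penicillin", "ige_mediated": true } ],
  "observations": [
    { "kind": "egfr", "value": 78, "observed_at": "2017-01-11T06:00:00Z" },
    { "kind": "neutrophils", "value": 4.2, "observed_at": "2017-01-11T06:00:00Z" }
  ],
  "cultures": [
    { "specimen": "blood", "collected_at": "2016-12-20T10:00:00Z",
      "organism": "Escherichia coli",
      "antibiogram": { "ciprofloxacin": "S", "amoxicillin": "R" } }
  ],
  "prescriptions": [
    { "atc": "J01CR05", "drug": "piperacillin-tazobactam",
      "dose_amount": 4000, "dose_unit": "mg", "route": "iv",
      "interval_hours": 6,
      "start": "2017-01-11T14:00:00Z", "stop": "2017-01-16T14:00:00Z",
      "perioperative_context": null,   // pre | intra | post | null
      "other_indication": null,        // perioperative cefazolin only
      "protocol_tag": null,            // sdd | neutropenia | copd | null
      "splenectomy_date": null }       // pheneticillin rule only
  ]
}
```

Constraints enforced on read: `admission_end >= admission_start`,
prescription `stop >= start`, observation values `>= 0`, a culture with an
organism must carry a non-empty antibiogram. eGFR is in mL/min/1.73 m2,
neutrophils in 1e9/L; eGFR is an extracted observation, never computed here.

## CSV bundle

A directory with `patients.csv`, `prescriptions.csv`, `cultures.csv`,
`observations.csv`, joined on `patient_id`. Same columns as above, with
these encodings in `patients.csv`: `allergies` as
`class:ige;class:non_ige`, `diagnoses` as `a;b`; and in `cultures.csv`:
`antibiogram` as `drug=S;drug=R`.

## Sessions file (`sessions.jsonl`)

One session per line:

```json
{ "session_id": "S0001", "patient_id": "P00001", "diagnosis": "pneumonia",
  "at_time": "2017-01-11T12:00:00Z", "is_test": false,
  "advice": { "kind": "regimen", "terminal": "adv_severe",
              "diagnosis": "pneumonia", "at_time": "2017-01-11T12:00:00Z",
              "duration_days": [5, 7],
              "drugs": [ { "drug": "piperacillin-tazobactam", "route": "iv",
                           "dose_amount": 4000, "dose_unit": "mg",
                           "interval_hours": 6, "dose_consult": false } ],
              "deviation": null, "answer_trail": [] } }
```

`is_test` marks try-out sessions excluded from the usage-rate numerator.
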