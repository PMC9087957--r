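kb <- load_example_kb()

test_that("sessions start at the root and unknown diagnoses list the available ones", {
  p <- make_patient()
  s <- start_session(kb, p, "pneumonia", T0)
  expect_s3_class(s, "empirx_session")
  expect_equal(s$current_node, "q_onset")
  expect_equal(s$status, "in_progress")
  err <- tryCatch(start_session(kb, p, "otitis", T0), error = conditionMessage)
  for (d in cdss_diagnoses()) expect_match(err, d, fixed = TRUE)
})

test_that("bound questions are auto-answered from the record; unknowns stay manual", {
  # pregnancy: men are never asked
  s <- start_session(kb, make_patient(sex = "male"), "urinary_tract_infection", T0)
  s <- submit_answer(s, "uncomplicated")
  expect_true("q_pregnant" %in% s$answer_trail$node)
  expect_equal(s$answer_trail$source[s$answer_trail$node == "q_pregnant"], "auto")
  expect_equal(s$answer_trail$answer[s$answer_trail$node == "q_pregnant"], "no")

  # a recorded value answers it; a yes routes to the pregnancy regimen
  s <- start_session(kb, make_patient(pregnant = TRUE), "urinary_tract_infection", T0)
  s <- submit_answer(s, "uncomplicated")
  expect_equal(current_node_id <- s$current_node, "gate_uti_preg")

  # unknown pregnancy in a woman surfaces the question
  s <- start_session(kb, make_patient(pregnant = NA), "urinary_tract_infection", T0)
  s <- submit_answer(s, "uncomplicated")
  expect_equal(s$current_node, "q_pregnant")

  # a recorded IgE penicillin allergy auto-answers the allergy question;
  # absence of a record does not auto-answer "no"
  s <- start_session(kb, make_patient(allergies = ige_penicillin), "sepsis", T0)
  expect_equal(s$current_node, "gate_sep_pen")
  s <- start_session(kb, make_patient(), "sepsis", T0)
  expect_equal(s$current_node, "q_allergy_sep")
})

test_that("answers advance along edges and illegal answers list the legal ones", {
  s <- start_session(kb, make_patient(), "pneumonia", T0)
  expect_error(submit_answer(s, "maybe"), "hap.*cap|cap.*hap")
  s <- submit_answer(s, "cap")
  expect_equal(s$current_node, "q_curb")
  s2 <- submit_answer(s, "low")
  expect_equal(s2$current_node, "gate_cap_low")
  expect_error(submit_answer(s2, "yes"), "not a question")
})

test_that("the antibiogram gate is obligatory, attaches windowed cultures, and blocks advice until acknowledged", {
  cu <- function(days_ago) list(specimen = "urine",
                                collected_at = T0 - days_ago * 86400,
                                organism = "Escherichia coli",
                                antibiogram = c(amoxicillin = "S"))
  p <- make_patient(cultures = list(cu(10), cu(100), cu(300)))
  s <- start_session(kb, p, "sepsis", T0)
  s <- submit_answer(s, "no")
  expect_equal(s$current_node, "gate_sep")
  expect_error(generate_advice(s), "not complete")
  expect_error(acknowledge_gate(submit_answer(start_session(kb, p, "sepsis", T0), "no") |>
                                  acknowledge_gate()), "not a gate")
  s <- acknowledge_gate(s)
  expect_equal(s$status, "complete")
  att <- s$gate_cultures[["gate_sep"]]
  expect_length(att, 2L) # the 300-day-old culture is outside the window
  expect_true(att[[1]]$collected_at > att[[2]]$collected_at)
})

test_that("CURB-65 counts its five criteria and maps risk at 0-1/2/>=3", {
  expect_equal(curb65(FALSE, 5, 18, 120, 80, 40), list(score = 0L, risk = "low"))
  expect_equal(curb65(TRUE, 9, 32, 85, 55, 70), list(score = 5L, risk = "high"))
  expect_equal(curb65(FALSE, 9, 32, 120, 80, 40)$risk, "moderate")
  expect_equal(curb65(TRUE, 9, 32, 120, 80, 40)$risk, "high")
  # boundary values: urea strictly > 7; RR >= 30; SBP < 90; DBP <= 60; age >= 65
  expect_equal(curb65(FALSE, 7, 29, 90, 61, 64)$score, 0L)
  expect_equal(curb65(FALSE, 7.1, 30, 90, 60, 65)$score, 4L)
  expect_error(curb65(FALSE, -1, 18, 120, 80, 40), "negative")
})

test_that("ideal body weight follows Devine with a floor at the base value, and BMI is weight over height squared", {
  expect_equal(ideal_body_weight("male", 152.4), 50)
  expect_equal(ideal_body_weight("female", 152.4), 45.5)
  expect_equal(ideal_body_weight("male", 180), 74.99, tolerance = 0.001)
  expect_equal(ideal_body_weight("female", 140), 45.5) # floored
  expect_error(ideal_body_weight("male", 0), "positive")
  expect_equal(bmi(80, 200), 20)
  expect_equal(bmi(45, 150), 20)
  expect_error(bmi(-1, 170), "positive")
  set.seed(1)
  for (i in 1:25) {
    w <- runif(1, 40, 150); h <- runif(1, 140, 210)
    expect_equal(bmi(w, h), w / (h / 100)^2)
  }
})

test_that("dose selection resolves renal bands, pregnancy restrictions and weight bases", {
  wctx <- list(weight_kg = 80, height_cm = 180, sex = "male")
  d <- select_dose("piperacillin-tazobactam", kb, egfr = 80, weight_ctx = wctx)
  expect_equal(d$dose_amount, 4000); expect_equal(d$interval_hours, 6)
  d <- select_dose("piperacillin-tazobactam", kb, egfr = 35, weight_ctx = wctx)
  expect_equal(d$interval_hours, 8)
  # half-open bands: 50 belongs to the upper band, 30 to [30,50)
  expect_equal(select_dose("piperacillin-tazobactam", kb, egfr = 50)$interval_hours, 6)
  expect_equal(select_dose("piperacillin-tazobactam", kb, egfr = 30)$interval_hours, 8)
  # renally banded table with no eGFR -> consult; renally flat table doses anyway
  expect_true(select_dose("piperacillin-tazobactam", kb, egfr = NULL)$consult)
  expect_false(select_dose("ceftriaxone", kb, egfr = NULL)$consult)
  # explicit consult band
  expect_true(select_dose("piperacillin-tazobactam", kb, egfr = 5)$consult)
  # pregnancy-disallowed row falls through to consult
  expect_true(select_dose("ciprofloxacin", kb, egfr = 80, pregnant = TRUE)$consult)
  expect_false(select_dose("ciprofloxacin", kb, egfr = 80, pregnant = FALSE)$consult)
  # gentamicin: 5 mg/kg on Devine ideal body weight, total in mg
  d <- select_dose("gentamicin", kb, egfr = 80, weight_ctx = wctx)
  expect_equal(d$weight_used$basis, "ideal")
  expect_equal(d$dose_amount, round(5 * ideal_body_weight("male", 180)))
  expect_equal(d$dose_unit, "mg")
  expect_true(select_dose("gentamicin", kb, egfr = 80,
                          weight_ctx = list(sex = "male"))$consult)
  expect_error(select_dose("linezolid", kb, egfr = 80), "no dose rule table")
})

test_that("deviation picks the first conflict-free alternative, or refers to the specialist", {
  reg <- kb$diagnoses$pneumonia$nodes$adv_severe$regimen # pip-tazo, alt cipro
  res_cult <- list(list(specimen = "blood", collected_at = T0 - 86400,
                        organism = "Escherichia coli",
                        antibiogram = c("piperacillin-tazobactam" = "R",
                                        ciprofloxacin = "S")))
  none <- apply_deviation(reg, list(), empty_al <- data.frame(
    drug_class = character(), ige_mediated = logical()))
  expect_null(none$deviation)
  expect_equal(none$regimen, reg)

  dev <- apply_deviation(reg, res_cult, empty_al)
  expect_equal(dev$deviation$reason, "resistance")
  expect_equal(dev$regimen$drugs[[1]]$drug, "ciprofloxacin")

  # intermediate results do not trigger deviation unless asked to
  int_cult <- list(list(specimen = "blood", collected_at = T0 - 86400,
                        organism = "Escherichia coli",
                        antibiogram = c("piperacillin-tazobactam" = "I")))
  expect_null(apply_deviation(reg, int_cult, empty_al)$deviation)
  expect_equal(apply_deviation(reg, int_cult, empty_al,
                               treat_intermediate_as_resistant = TRUE
                               )$deviation$reason, "resistance")

  # allergy conflicts by drug class
  dev <- apply_deviation(reg, list(), ige_penicillin)
  expect_equal(dev$deviation$reason, "allergy")
  expect_equal(dev$regimen$drugs[[1]]$drug, "ciprofloxacin")

  # every alternative conflicted -> consult
  all_r <- list(list(specimen = "blood", collected_at = T0 - 86400,
                     organism = "Escherichia coli",
                     antibiogram = c("piperacillin-tazobactam" = "R",
                                     ciprofloxacin = "R")))
  dev <- apply_deviation(reg, all_r, empty_al)
  expect_null(dev$regimen)
  expect_equal(dev$deviation$to, "consult")
})

test_that("complete pathways produce the guideline advice with dose and route", {
  p <- make_patient(egfr = 80)
  s <- replay_answers(kb, p, "pneumonia",
                      c(q_onset = "hap", q_allergy_hap = "no"), T0)
  adv <- generate_advice(s)
  expect_equal(adv$kind, "regimen")
  expect_equal(adv$drugs[[1]]$drug, "piperacillin-tazobactam")
  expect_equal(adv$drugs[[1]]$route, "iv")
  expect_equal(adv$drugs[[1]]$dose$dose_amount, 4000)

  s <- replay_answers(kb, make_patient(egfr = 80, pregnant = FALSE),
                      "urinary_tract_infection",
                      c(q_complicated = "uncomplicated"), T0)
  adv <- generate_advice(s)
  expect_equal(adv$drugs[[1]]$drug, "nitrofurantoin")
  expect_equal(adv$drugs[[1]]$route, "oral")

  # a consult terminal passes through unchanged
  s <- replay_answers(kb, make_patient(), "fever_unknown_origin",
                      c(q_neutro = "yes"), T0)
  expect_equal(generate_advice(s)$kind, "consult")

  # determinism: identical inputs, identical advice
  a1 <- generate_advice(replay_answers(kb, p, "pneumonia",
                                       c(q_onset = "hap", q_allergy_hap = "no"), T0))
  a2 <- generate_advice(replay_answers(kb, p, "pneumonia",
                                       c(q_onset = "hap", q_allergy_hap = "no"), T0))
  expect_equal(a1, a2)
})

test_that("a manual override rewinds the session and keeps the superseded answers", {
  p <- make_patient(pregnant = TRUE, egfr = 80)
  s <- replay_answers(kb, p, "urinary_tract_infection",
                      c(q_complicated = "uncomplicated"), T0)
  expect_equal(s$current_node, "adv_uti_preg")
  s2 <- override_answer(s, "q_pregnant", "no")
  while (s2$status == "in_progress") s2 <- acknowledge_gate(s2)
  expect_equal(s2$current_node, "adv_uti_unc")
  expect_equal(s2$answer_trail$source[s2$answer_trail$node == "q_pregnant"], "manual")
  expect_true("q_pregnant" %in% s2$superseded_trail$node)
})

test_that("advice never strays outside the knowledge base nor into recorded conflicts", {
  set.seed(404)
  allowed_for <- function(diagnosis, terminal) {
    nd <- kb$diagnoses[[diagnosis]]$nodes[[terminal]]
    if (nd$consult) character() else
      unique(unlist(lapply(c(list(nd$regimen), nd$regimen$alternatives),
                           function(r) vapply(r$drugs, `[[`, "", "drug"))))
  }
  for (i in 1:40) {
    dx <- sample(cdss_diagnoses(), 1)
    has_all <- runif(1) < 0.4
    has_res <- runif(1) < 0.4
    cult <- if (has_res) list(list(
      specimen = "blood", collected_at = T0 - 30 * 86400,
      organism = "Escherichia coli",
      antibiogram = c("piperacillin-tazobactam" = "R", ceftriaxone = "R",
                      amoxicillin = "R", nitrofurantoin = "R",
                      ciprofloxacin = "S", gentamicin = "S",
                      metronidazole = "S", doxycycline = "S"))) else list()
    p <- make_patient(egfr = sample(c(90, 40, 20), 1),
                      allergies = if (has_all) ige_penicillin else NULL,
                      cultures = cult)
    adv <- generate_advice(random_walk(kb, p, dx, T0))
    if (adv$kind == "consult") next
    drugs <- vapply(adv$drugs, `[[`, "", "drug")
    expect_true(all(drugs %in% allowed_for(dx, adv$terminal)))
    # deviation safety: no advised drug is R in the windowed history
    for (cu in cultures_in_window(p, T0)) {
      ab <- cu$antibiogram
      expect_false(any(names(ab) %in% drugs & ab == "R"))
    }
    # ... nor hit by a recorded allergy
    if (has_all) expect_false(any(drug_class_of(drugs) == "penicillin"))
  }
})
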