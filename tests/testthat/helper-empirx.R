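# Shared fixtures and independent oracles.

T0 <- as.POSIXct("2017-01-11 12:00:00", tz = "UTC")

example_kb_path <- function()
  system.file("extdata", "example-kb.yaml", package = "empirx")

# A patient whose record resolves no data binding: every question surfaces
# as manual, so enumerated answer sequences replay one-to-one.
make_patient <- function(patient_id = "PT1", sex = "female",
                         birth_date = "1955-06-01",
                         ward = "internal_medicine",
                         admission_start = "2017-01-10 08:00:00",
                         admission_end = "2017-01-20 08:00:00",
                         weight_kg = 70, height_cm = 165, pregnant = NA,
                         allergies = NULL, observations = NULL,
                         cultures = list(), prescriptions = NULL,
                         diagnoses = character(), egfr = NULL) {
  if (!is.null(egfr)) {
    observations <- rbind(observations,
                          data.frame(kind = "egfr", value = egfr,
                                     observed_at = T0 - 6 * 3600,
                                     stringsAsFactors = FALSE))
  }
  args <- list(patient_id = patient_id, birth_date = birth_date, sex = sex,
               ward = ward, admission_start = admission_start,
               admission_end = admission_end, weight_kg = weight_kg,
               height_cm = height_cm, pregnant = pregnant,
               cultures = cultures, diagnoses = diagnoses)
  if (!is.null(allergies)) args$allergies <- allergies
  if (!is.null(observations)) args$observations <- observations
  if (!is.null(prescriptions)) args$prescriptions <- prescriptions
  do.call(new_patient, args)
}

make_rx <- function(drug = "amoxicillin", atc = "J01CA04",
                    dose_amount = 500, dose_unit = "mg", route = "oral",
                    interval_hours = 8,
                    start = T0 + 2 * 3600, stop = start + 5 * 86400,
                    perioperative_context = NA_character_,
                    other_indication = NA, protocol_tag = NA_character_,
                    splenectomy_date = as.Date(NA)) {
  data.frame(atc = atc, drug = drug, dose_amount = dose_amount,
             dose_unit = dose_unit, route = route,
             interval_hours = interval_hours, start = start, stop = stop,
             perioperative_context = perioperative_context,
             other_indication = other_indication,
             protocol_tag = protocol_tag,
             splenectomy_date = splenectomy_date, stringsAsFactors = FALSE)
}

ige_penicillin <- data.frame(drug_class = "penicillin", ige_mediated = TRUE,
                             stringsAsFactors = FALSE)

# Independent depth-first path enumeration over the RAW parsed YAML file
# (no package data structures involved).
oracle_paths <- function(raw_pathway) {
  nodes <- raw_pathway$nodes
  res <- list()
  rec <- function(nid, acc) {
    nd <- nodes[[nid]]
    if (identical(nd$kind, "advice")) {
      res[[length(res) + 1L]] <<- list(terminal = nid, answers = acc)
    } else if (identical(nd$kind, "gate")) {
      rec(nd[["next"]], acc)
    } else {
      for (a in names(nd$edges))
        rec(nd$edges[[a]], c(acc, stats::setNames(a, nid)))
    }
  }
  rec(raw_pathway$root, character())
  res
}

# Independent all-rules prophylaxis oracle: evaluates every rule as a
# boolean and returns the first true one in the documented order.
oracle_prophylaxis <- function(pr) {
  mg <- if (is.na(pr$dose_amount) || is.na(pr$dose_unit)) NA_real_
        else pr$dose_amount * switch(pr$dose_unit, mg = 1, g = 1000, NA_real_)
  dur <- if (is.null(pr$stop) || is.na(pr$stop)) NA_real_
         else as.numeric(difftime(pr$stop, pr$start, units = "hours"))
  splen_days <- if (is.null(pr$splenectomy_date) || is.na(pr$splenectomy_date))
    NA_real_
  else as.numeric(difftime(pr$start,
                           as.POSIXct(pr$splenectomy_date, tz = "UTC"),
                           units = "days"))
  rules <- c(
    duration_lt_48h = !is.na(dur) && dur < 48,
    cotrimoxazole_480 = identical(pr$drug, "cotrimoxazole") &&
      !is.na(mg) && mg == 480,
    perioperative_cefazolin = identical(pr$drug, "cefazolin") &&
      !is.na(pr$perioperative_context) &&
      pr$perioperative_context %in% c("pre", "intra", "post") &&
      !isTRUE(pr$other_indication),
    sdd = identical(pr$protocol_tag, "sdd"),
    neutropenia = identical(pr$protocol_tag, "neutropenia"),
    copd = identical(pr$protocol_tag, "copd"),
    pheneticillin_post_splenectomy = identical(pr$drug, "pheneticillin") &&
      !is.na(splen_days) && splen_days >= 0 && splen_days <= 730)
  if (any(rules)) names(rules)[which(rules)[1L]] else "none"
}

random_prescription <- function() {
  start <- T0 + sample(-100:100, 1) * 3600
  stop_h <- sample(c(NA, 12, 36, 47, 47.9, 48, 49, 120, 240), 1)
  list(
    drug = sample(c("cefazolin", "cotrimoxazole", "pheneticillin",
                    "amoxicillin", "cefuroxime"), 1),
    atc = "J01XX00",
    dose_amount = sample(c(480, 960, 1000, 0.48), 1),
    dose_unit = sample(c("mg", "g"), 1),
    route = sample(c("iv", "oral"), 1),
    interval_hours = 8,
    start = start,
    stop = if (is.na(stop_h)) as.POSIXct(NA) else start + stop_h * 3600,
    perioperative_context = sample(c(NA, "pre", "intra", "post"), 1),
    other_indication = sample(list(NA, TRUE, FALSE), 1)[[1]],
    protocol_tag = sample(c(NA, "sdd", "neutropenia", "copd"), 1),
    splenectomy_date = if (stats::runif(1) < 0.5) as.Date(NA)
      else as.Date(start) - sample(c(-10, 100, 600, 729, 730, 731, 1200), 1))
}

# Drive a session to completion, answering surfaced questions at random.
random_walk <- function(kb, patient, diagnosis, at_time = T0) {
  s <- start_session(kb, patient, diagnosis, at_time)
  while (s$status == "in_progress") {
    nd <- kb$diagnoses[[s$diagnosis]]$nodes[[s$current_node]]
    if (nd$kind == "gate") s <- acknowledge_gate(s)
    else s <- submit_answer(s, sample(names(nd$edges), 1))
  }
  s
}
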