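# Seeded synthetic cohort generator. Emulates the statistical structure the
# stewardship evaluation assumes: ward strata, a configurable prevalence of
# CDSS-included diagnoses (pneumonia and UTI most frequent), an adherence
# mixture (complete/partial/none) realized as prescriptions against the
# example knowledge base's own advice, prophylaxis-only patients, prior
# cultures resistant to first-choice drugs, and test/try-out sessions.

.dx_weights <- c(pneumonia = 0.30, urinary_tract_infection = 0.28,
                 sepsis = 0.14, fever_unknown_origin = 0.10,
                 secondary_peritonitis = 0.08, meningitis = 0.05,
                 liver_abscess = 0.05)

.dx_first_choice <- c(pneumonia = "piperacillin-tazobactam",
                      urinary_tract_infection = "nitrofurantoin",
                      sepsis = "ceftriaxone",
                      fever_unknown_origin = "ceftriaxone",
                      meningitis = "ceftriaxone",
                      secondary_peritonitis = "ceftriaxone",
                      liver_abscess = "ceftriaxone")

# drug -> dose, unit, interval_hours, route used for background therapy
.bg_dose <- list(
  "piperacillin-tazobactam" = list(4000, "mg", 6, "iv"),
  "nitrofurantoin" = list(50, "mg", 6, "oral"),
  "ceftriaxone" = list(2000, "mg", 24, "iv"),
  "ciprofloxacin" = list(400, "mg", 12, "iv"),
  "amoxicillin" = list(500, "mg", 8, "oral"),
  "cefuroxime" = list(750, "mg", 8, "iv"),
  "clindamycin" = list(600, "mg", 8, "iv"))

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the evaluation's study conditions: ~40.3% of antibiotic
#' users have a CDSS-included diagnosis, the CDSS is consulted for 12.5% of
#' eligible patients, test sessions make up ~8% of all sessions (15/184),
#' and followed advices split 55/15/30 into complete/partial/none.
#'
#' @param n_patients number of patients.
#' @param ward_weights named probabilities of admission wards (normalized).
#' @param eligible_prevalence probability a patient has a CDSS-included
#'   diagnosis.
#' @param adherence_mixture probabilities (complete, partial, none) of the
#'   intended adherence category of an advised patient; must sum to 1.
#' @param prophylaxis_only_rate probability a patient receives only
#'   prophylactic antibiotics (drawn independently of eligibility).
#' @param resistance_rate probability an advised patient has a prior culture
#'   resistant to first-choice drugs.
#' @param session_rate probability an eligible (non-prophylaxis-only)
#'   patient generates a real CDSS session.
#' @param test_session_rate expected fraction of all sessions that are
#'   test/try-out sessions.
#' @param seed integer RNG seed.
#' @return an `empirx_cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          ward_weights = c(internal_medicine = 0.30,
                                           surgery = 0.20, pulmonology = 0.15,
                                           urology = 0.10, neurology = 0.10,
                                           icu = 0.15),
                          eligible_prevalence = 0.403,
                          adherence_mixture = c(complete = 0.55,
                                                partial = 0.15, none = 0.30),
                          prophylaxis_only_rate = 0.10,
                          resistance_rate = 0.10,
                          session_rate = 0.125,
                          test_session_rate = 0.08,
                          seed = 1L) {
  probs <- c(eligible_prevalence, prophylaxis_only_rate, resistance_rate,
             session_rate, test_session_rate, adherence_mixture, ward_weights)
  if (any(probs < 0 | probs > 1))
    stop("cohort_config: probabilities must be in [0, 1]")
  if (abs(sum(adherence_mixture) - 1) > 1e-9)
    stop("cohort_config: adherence_mixture must sum to 1")
  if (test_session_rate >= 1)
    stop("cohort_config: test_session_rate must be < 1")
  structure(list(n_patients = as.integer(n_patients),
                 ward_weights = ward_weights / sum(ward_weights),
                 eligible_prevalence = eligible_prevalence,
                 adherence_mixture = adherence_mixture,
                 prophylaxis_only_rate = prophylaxis_only_rate,
                 resistance_rate = resistance_rate,
                 session_rate = session_rate,
                 test_session_rate = test_session_rate,
                 seed = as.integer(seed)),
            class = "empirx_cohort_config")
}

random_walk_advice <- function(kb, patient, diagnosis, at_time) {
  s <- start_session(kb, patient, diagnosis, at_time)
  guard <- 0L
  while (s$status == "in_progress") {
    guard <- guard + 1L
    if (guard > 100L) stop("random walk did not terminate")
    nd <- current_node(s)
    if (nd$kind == "gate") s <- acknowledge_gate(s)
    else s <- submit_answer(s, sample(names(nd$edges), 1L))
  }
  generate_advice(s)
}

realization_rows <- function(advice, category, partial_mode, at_time) {
  drugs <- advice$drugs
  dur <- advice$duration_days[[1L]]
  if (is.na(dur)) dur <- 5
  start <- at_time + 2 * 3600
  row_for <- function(d, route = NULL, interval = NULL) {
    data.frame(atc = atc_of(d$drug), drug = d$drug,
               dose_amount = d$dose$dose_amount, dose_unit = d$dose$dose_unit,
               route = route %||% d$route,
               interval_hours = interval %||% d$dose$interval_hours,
               start = start, stop = start + dur * 86400,
               perioperative_context = NA_character_,
               other_indication = NA, protocol_tag = NA_character_,
               splenectomy_date = as.Date(NA),
               stringsAsFactors = FALSE)
  }
  if (category == "complete") {
    do.call(rbind, lapply(drugs, row_for))
  } else if (category == "partial") {
    if (partial_mode == "drop" && length(drugs) >= 2L) {
      do.call(rbind, lapply(drugs[-length(drugs)], row_for))
    } else {
      # change route of the first drug, keep the rest exact
      first <- drugs[[1L]]
      flipped <- if (first$route == "iv") "oral" else "iv"
      rbind(row_for(first, route = flipped),
            if (length(drugs) > 1L)
              do.call(rbind, lapply(drugs[-1L], row_for)))
    }
  } else { # none: a systemic antibacterial outside the advised set
    pool <- setdiff(c("clindamycin", "cefuroxime"),
                    vapply(drugs, function(d) d$drug, character(1)))
    spec <- .bg_dose[[pool[[1L]]]]
    data.frame(atc = atc_of(pool[[1L]]), drug = pool[[1L]],
               dose_amount = spec[[1L]], dose_unit = spec[[2L]],
               route = spec[[4L]], interval_hours = spec[[3L]],
               start = start, stop = start + 5 * 86400,
               perioperative_context = NA_character_,
               other_indication = NA, protocol_tag = NA_character_,
               splenectomy_date = as.Date(NA), stringsAsFactors = FALSE)
  }
}

resistant_culture <- function(at_time) {
  list(specimen = "blood", collected_at = at_time - 40 * 86400,
       organism = "Escherichia coli",
       antibiogram = c("piperacillin-tazobactam" = "R", amoxicillin = "R",
                       ceftriaxone = "R", nitrofurantoin = "R",
                       ciprofloxacin = "S", gentamicin = "S",
                       metronidazole = "S", doxycycline = "S"))
}

#' Generate a seeded synthetic cohort with CDSS sessions and ground truth
#'
#' Patients are drawn per ward weights; a Bernoulli(`eligible_prevalence`)
#' flag assigns each patient a CDSS-included diagnosis (pneumonia and UTI
#' most frequent). Real sessions are generated for eligible patients by
#' replaying a random path through the example knowledge base with the
#' engine itself; the intended adherence category is then realized as
#' prescriptions against the generated advice (partial via drop-one-drug or
#' route change). Prophylaxis-only patients receive exactly one
#' rule-matching prophylactic course. Fully reproducible from the seed.
#'
#' @param config an `empirx_cohort_config`.
#' @return list with `cohort` (list of `empirx_patient`), `sessions` (list
#'   of session records) and `truth` (data frames `patients`, `sessions`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "empirx_cohort_config"))
  n <- config$n_patients
  truth_p_empty <- data.frame(patient_id = character(), eligible = logical(),
                              prophylaxis_only = logical(),
                              adherence_category = character(),
                              partial_mode = character(),
                              stringsAsFactors = FALSE)
  truth_s_empty <- data.frame(session_id = character(), is_test = logical(),
                              stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(cohort = list(), sessions = list(),
                truth = list(patients = truth_p_empty, sessions = truth_s_empty)))
  kb <- load_example_kb()

  with_seed(config$seed, {
    ids <- sprintf("P%05d", seq_len(n))
    ward <- sample(names(config$ward_weights), n, TRUE,
                   prob = config$ward_weights)
    sex <- sample(c("male", "female"), n, TRUE)
    age <- sample(18:92, n, TRUE)
    adm_start <- as.POSIXct("2016-12-01 00:00:00", tz = "UTC") +
      round(stats::runif(n, 0, 180 * 86400) / 60) * 60
    birth <- as.Date(adm_start) - (age * 366L + 30L)
    height <- pmin(pmax(round(stats::rnorm(n, ifelse(sex == "male", 178, 165), 7), 1),
                        148), 205)
    weight <- pmin(pmax(round(stats::rnorm(n, ifelse(sex == "male", 82, 70), 12), 1),
                        42), 160)
    pregnant <- rep(FALSE, n)
    fertile <- sex == "female" & age < 50
    pregnant[fertile] <- stats::runif(sum(fertile)) < 0.04
    unknown <- fertile & stats::runif(n) < 0.10
    pregnant[unknown] <- NA
    has_allergy <- stats::runif(n) < 0.05
    eligible <- stats::runif(n) < config$eligible_prevalence
    proph <- stats::runif(n) < config$prophylaxis_only_rate
    diagnosis <- rep(NA_character_, n)
    if (any(eligible))
      diagnosis[eligible] <- sample(names(.dx_weights), sum(eligible), TRUE,
                                    prob = .dx_weights)
    sess <- eligible & !proph & stats::runif(n) < config$session_rate
    res_flag <- sess & stats::runif(n) < config$resistance_rate
    intended <- rep(NA_character_, n)
    if (any(sess))
      intended[sess] <- sample(names(config$adherence_mixture), sum(sess),
                               TRUE, prob = config$adherence_mixture)
    partial_mode <- rep(NA_character_, n)
    pm <- sess & intended == "partial"
    pm[is.na(pm)] <- FALSE
    if (any(pm)) partial_mode[pm] <- sample(c("drop", "modify"), sum(pm), TRUE)
    span_h <- sample(30:336, n, TRUE)
    span_h[sess] <- pmax(span_h[sess], 96L)
    adm_end <- adm_start + span_h * 3600
    egfr <- pmin(pmax(round(stats::rnorm(n, 85, 25)), 8), 150)
    neut <- pmax(round(stats::rnorm(n, 5, 2), 1), 0.1)
    proph_mode <- sample(c("periop", "cotrim", "sdd"), n, TRUE)
    at_time <- adm_start + 36 * 3600

    # observations: one eGFR + one neutrophil count at admission + 2 h
    obs_at <- adm_start + 2 * 3600
    obs_df <- data.frame(
      patient_id = rep(ids, 2L),
      kind = rep(c("egfr", "neutrophils"), each = n),
      value = c(egfr, neut),
      observed_at = rep(obs_at, 2L), stringsAsFactors = FALSE)
    obs_df <- obs_df[order(match(obs_df$patient_id, ids)), , drop = FALSE]
    obs_split <- split(obs_df[-1L], factor(obs_df$patient_id, levels = ids))

    # background / prophylactic prescriptions (session patients get their
    # prescriptions from the adherence realization instead)
    bg_idx <- which(!sess)
    mk_bg <- function(i) {
      if (proph[i]) {
        mode <- proph_mode[i]
        if (mode == "periop") {
          c(atc = "J01DB04", drug = "cefazolin", dose_amount = 1000,
            dose_unit = "mg", route = "iv", interval_hours = 8,
            start_off = 1, dur_h = 72, ctx = "intra", tag = NA_character_)
        } else if (mode == "cotrim") {
          c(atc = "J01EE01", drug = "cotrimoxazole", dose_amount = 480,
            dose_unit = "mg", route = "oral", interval_hours = 24,
            start_off = 4, dur_h = 240, ctx = NA_character_, tag = NA_character_)
        } else {
          c(atc = "J01DC02", drug = "cefuroxime", dose_amount = 750,
            dose_unit = "mg", route = "iv", interval_hours = 8,
            start_off = 4, dur_h = 168, ctx = NA_character_, tag = "sdd")
        }
      } else {
        drug <- if (eligible[i]) .dx_first_choice[[diagnosis[i]]]
                else c("cefuroxime", "clindamycin")[1L + (i %% 2L)]
        spec <- .bg_dose[[drug]]
        c(atc = atc_of(drug), drug = drug, dose_amount = spec[[1L]],
          dose_unit = spec[[2L]], route = spec[[4L]],
          interval_hours = spec[[3L]], start_off = 6, dur_h = 120,
          ctx = NA_character_, tag = NA_character_)
      }
    }
    bg <- lapply(bg_idx, mk_bg)
    bg_df <- data.frame(
      patient_id = ids[bg_idx],
      atc = vapply(bg, `[[`, "", "atc"),
      drug = vapply(bg, `[[`, "", "drug"),
      dose_amount = as.numeric(vapply(bg, `[[`, "", "dose_amount")),
      dose_unit = vapply(bg, `[[`, "", "dose_unit"),
      route = vapply(bg, `[[`, "", "route"),
      interval_hours = as.numeric(vapply(bg, `[[`, "", "interval_hours")),
      start = adm_start[bg_idx] +
        as.numeric(vapply(bg, `[[`, "", "start_off")) * 3600,
      stop = adm_start[bg_idx] +
        as.numeric(vapply(bg, `[[`, "", "start_off")) * 3600 +
        as.numeric(vapply(bg, `[[`, "", "dur_h")) * 3600,
      perioperative_context = vapply(bg, `[[`, "", "ctx"),
      other_indication = rep(NA, length(bg_idx)),
      protocol_tag = vapply(bg, `[[`, "", "tag"),
      splenectomy_date = rep(as.Date(NA), length(bg_idx)),
      stringsAsFactors = FALSE)
    bg_split <- split(bg_df[-1L], factor(bg_df$patient_id, levels = ids))

    cohort <- vector("list", n)
    for (i in seq_len(n)) {
      al <- if (has_allergy[i])
        data.frame(drug_class = "penicillin", ige_mediated = TRUE,
                   stringsAsFactors = FALSE)
      else empty_allergies()
      ob <- obs_split[[i]]; rownames(ob) <- NULL
      pr <- bg_split[[i]]
      if (is.null(pr) || !nrow(pr)) pr <- empty_prescriptions()
      rownames(pr) <- NULL
      cohort[[i]] <- new_patient(
        patient_id = ids[i], birth_date = birth[i], sex = sex[i],
        ward = ward[i], admission_start = adm_start[i],
        admission_end = adm_end[i], weight_kg = weight[i],
        height_cm = height[i], pregnant = pregnant[i], allergies = al,
        observations = ob,
        cultures = if (res_flag[i]) list(resistant_culture(at_time[i]))
                   else list(),
        prescriptions = pr,
        diagnoses = if (eligible[i]) diagnosis[i] else character())
    }

    # real sessions: engine replay of a random path, then adherence
    # realization against the generated advice
    sessions <- list()
    realized <- rep(NA_character_, n)
    for (i in which(sess)) {
      adv <- random_walk_advice(kb, cohort[[i]], diagnosis[i], at_time[i])
      sid <- sprintf("S%04d", length(sessions) + 1L)
      sessions[[length(sessions) + 1L]] <-
        list(session_id = sid, patient_id = ids[i], diagnosis = diagnosis[i],
             at_time = at_time[i], is_test = FALSE, advice = adv)
      realizable <- adv$kind == "regimen" &&
        !any(vapply(adv$drugs, function(d) d$dose$consult, logical(1)))
      if (realizable) {
        cohort[[i]]$prescriptions <-
          realization_rows(adv, intended[i], partial_mode[i], at_time[i])
        realized[i] <- intended[i]
      } else {
        # advice ended in a consult; give ordinary empirical therapy so the
        # patient still qualifies for the evaluable cohort
        drug <- .dx_first_choice[[diagnosis[i]]]
        spec <- .bg_dose[[drug]]
        cohort[[i]]$prescriptions <- data.frame(
          atc = atc_of(drug), drug = drug, dose_amount = spec[[1L]],
          dose_unit = spec[[2L]], route = spec[[4L]],
          interval_hours = spec[[3L]],
          start = adm_start[i] + 6 * 3600,
          stop = adm_start[i] + 6 * 3600 + 120 * 3600,
          perioperative_context = NA_character_, other_indication = NA,
          protocol_tag = NA_character_, splenectomy_date = as.Date(NA),
          stringsAsFactors = FALSE)
      }
    }

    # test / try-out sessions (no signs of infection; advice discarded in
    # the evaluation but generated all the same)
    n_real <- length(sessions)
    r <- config$test_session_rate
    n_test <- if (n_real > 0L && r > 0)
      stats::rbinom(1L, n_real, r / (1 - r)) else 0L
    n_test <- min(n_test, n)
    if (n_test > 0L) {
      testers <- sample.int(n, n_test)
      test_dx <- sample(cdss_diagnoses(), n_test, TRUE)
      for (j in seq_len(n_test)) {
        i <- testers[j]
        adv <- random_walk_advice(kb, cohort[[i]], test_dx[j],
                                  adm_start[i] + 24 * 3600)
        sid <- sprintf("S%04d", length(sessions) + 1L)
        sessions[[length(sessions) + 1L]] <-
          list(session_id = sid, patient_id = ids[i], diagnosis = test_dx[j],
               at_time = adm_start[i] + 24 * 3600, is_test = TRUE,
               advice = adv)
      }
    }

    truth <- list(
      patients = data.frame(patient_id = ids, eligible = eligible,
                            prophylaxis_only = proph,
                            adherence_category = realized,
                            partial_mode = ifelse(is.na(realized) |
                                                    realized != "partial",
                                                  NA_character_, partial_mode),
                            stringsAsFactors = FALSE),
      sessions = data.frame(
        session_id = vapply(sessions, `[[`, "", "session_id"),
        is_test = vapply(sessions, function(s) s$is_test, logical(1)),
        stringsAsFactors = FALSE))
    list(cohort = cohort, sessions = sessions, truth = truth)
  })
}
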