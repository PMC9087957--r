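# Advisor engine: traverses a diagnosis pathway for a patient, answering
# bound questions automatically from the record where the data are present
# and fresh, stopping at manual questions and at the obligatory
# antibiogram-review gate, and composing the final advice (deviation for
# resistance/allergy, then renal/weight-refined dose selection per drug).

empty_trail <- function()
  data.frame(node = character(), answer = character(), source = character(),
             stringsAsFactors = FALSE)

# Resolve a question's data binding against the patient record.
# Returns an answer string, or NA when the question must be asked manually.
# Positive-evidence policy for allergies: an absent record never auto-answers
# "no" (records can be incomplete); pregnancy is always asked for women with
# unknown status, and never asked for men.
resolve_binding <- function(binding, patient, at_time) {
  if (is.null(binding)) return(NA_character_)
  switch(binding,
    pregnant = {
      if (identical(patient$sex, "male")) "no"
      else if (isTRUE(patient$pregnant)) "yes"
      else if (isFALSE(patient$pregnant)) "no"
      else NA_character_
    },
    allergy_penicillin_ige = {
      al <- patient$allergies
      if (nrow(al) && any(al$ige_mediated &
                          (al$drug_class %in% c("penicillin", "beta_lactam"))))
        "yes" else NA_character_
    },
    neutropenic = {
      obs <- patient$observations
      obs <- obs[obs$kind == "neutrophils" & obs$observed_at <= at_time, ,
                 drop = FALSE]
      if (!nrow(obs)) return(NA_character_)
      if (obs$value[which.max(obs$observed_at)] < 0.5) "yes" else "no"
    },
    NA_character_)
}

advance_auto <- function(s) {
  pw <- s$kb$diagnoses[[s$diagnosis]]
  repeat {
    nd <- pw$nodes[[s$current_node]]
    if (nd$kind == "advice") {
      s$status <- "complete"
      break
    }
    if (nd$kind == "gate") break
    ans <- resolve_binding(nd$data_binding, s$patient, s$at_time)
    if (is.na(ans) || !ans %in% names(nd$edges)) break
    s$answer_trail <- rbind(s$answer_trail,
                            data.frame(node = nd$id, answer = ans,
                                       source = "auto", stringsAsFactors = FALSE))
    s$current_node <- nd$edges[[ans]]
  }
  s
}

#' Start an advisor session
#'
#' Places the session at the pathway root and auto-advances through any
#' questions answerable from the patient record.
#'
#' @param kb an `empirx_kb`.
#' @param patient an `empirx_patient`.
#' @param diagnosis working diagnosis (must be in `kb`).
#' @param at_time timestamp of CDSS consultation; drives culture and eGFR
#'   windows.
#' @return an `empirx_session`.
#' @export
start_session <- function(kb, patient, diagnosis, at_time = Sys.time()) {
  stopifnot(inherits(kb, "empirx_kb"), inherits(patient, "empirx_patient"))
  if (!diagnosis %in% names(kb$diagnoses))
    stop(sprintf("unknown diagnosis '%s'; available diagnoses: %s",
                 diagnosis, paste(names(kb$diagnoses), collapse = ", ")))
  s <- structure(list(kb = kb, patient = patient, diagnosis = diagnosis,
                      at_time = parse_time(at_time),
                      current_node = kb$diagnoses[[diagnosis]]$root,
                      answer_trail = empty_trail(),
                      gates_acknowledged = character(),
                      gate_cultures = list(),
                      status = "in_progress"),
                 class = "empirx_session")
  advance_auto(s)
}

current_node <- function(s) s$kb$diagnoses[[s$diagnosis]]$nodes[[s$current_node]]

#' Answer the current question of a session
#'
#' @param session an in-progress `empirx_session` whose current node is a
#'   question.
#' @param answer one of the question's answer values.
#' @return the advanced session.
#' @export
submit_answer <- function(session, answer) {
  stopifnot(inherits(session, "empirx_session"))
  if (session$status != "in_progress")
    stop("session is already complete")
  nd <- current_node(session)
  if (nd$kind != "question")
    stop("current node '", nd$id, "' is a ", nd$kind, ", not a question")
  if (!answer %in% names(nd$edges))
    stop(sprintf("illegal answer '%s' for '%s'; legal answers: %s",
                 answer, nd$id, paste(names(nd$edges), collapse = ", ")))
  session$answer_trail <- rbind(session$answer_trail,
                                data.frame(node = nd$id, answer = answer,
                                           source = "manual",
                                           stringsAsFactors = FALSE))
  session$current_node <- nd$edges[[answer]]
  advance_auto(session)
}

#' Acknowledge the antibiogram-review gate
#'
#' The physician is obliged to review the culture history before the
#' pathway proceeds. Acknowledging attaches the cultures inside the gate's
#' window (newest first) to the session and resumes traversal.
#'
#' @param session an `empirx_session` stopped at a gate node.
#' @return the advanced session; reviewed cultures are in
#'   `session$gate_cultures[[gate_id]]`.
#' @export
acknowledge_gate <- function(session) {
  stopifnot(inherits(session, "empirx_session"))
  nd <- current_node(session)
  if (nd$kind != "gate")
    stop("current node '", nd$id, "' is not a gate")
  session$gates_acknowledged <- c(session$gates_acknowledged, nd$id)
  session$gate_cultures[[nd$id]] <-
    cultures_in_window(session$patient, session$at_time, nd$window_days)
  session$current_node <- nd$next_node
  advance_auto(session)
}

#' Override an earlier (possibly automatic) answer
#'
#' Automatically bound values can be wrong or stale in the source system, so
#' a manual answer may overwrite an automatic one. The session is replayed
#' up to the overridden question; the trail keeps the superseded answers.
#'
#' @param session an `empirx_session`.
#' @param node_id id of a question already answered in this session.
#' @param answer the new (manual) answer.
#' @return a session re-advanced from the overridden question.
#' @export
override_answer <- function(session, node_id, answer) {
  tr <- session$answer_trail
  hit <- which(tr$node == node_id)
  if (!length(hit))
    stop("node '", node_id, "' has not been answered in this session")
  keep <- tr[seq_len(min(hit) - 1L), , drop = FALSE]
  pw <- session$kb$diagnoses[[session$diagnosis]]
  s <- session
  s$status <- "in_progress"
  s$gates_acknowledged <- character()
  s$gate_cultures <- list()
  # walk the graph along the retained answers, re-acknowledging gates that
  # were passed before the overridden question; the overridden node itself
  # must not be re-auto-answered, so no binding resolution happens here
  cur <- pw$root
  pass_gates <- function() {
    while (pw$nodes[[cur]]$kind == "gate") {
      nd <- pw$nodes[[cur]]
      s$gates_acknowledged <<- c(s$gates_acknowledged, nd$id)
      s$gate_cultures[[nd$id]] <<-
        cultures_in_window(s$patient, s$at_time, nd$window_days)
      cur <<- nd$next_node
    }
  }
  pass_gates()
  for (i in seq_len(nrow(keep))) {
    if (cur != keep$node[i])
      stop("cannot replay session up to node '", node_id, "'")
    cur <- pw$nodes[[cur]]$edges[[keep$answer[i]]]
    pass_gates()
  }
  if (cur != node_id)
    stop("cannot replay session up to node '", node_id, "'")
  nd <- pw$nodes[[cur]]
  if (!answer %in% names(nd$edges))
    stop(sprintf("illegal answer '%s' for '%s'; legal answers: %s",
                 answer, node_id, paste(names(nd$edges), collapse = ", ")))
  s$superseded_trail <- rbind(session$superseded_trail,
                              tr[min(hit):nrow(tr), , drop = FALSE])
  s$answer_trail <- rbind(keep,
                          data.frame(node = node_id, answer = answer,
                                     source = "manual", stringsAsFactors = FALSE))
  s$current_node <- nd$edges[[answer]]
  advance_auto(s)
}

#' Replay a full answer sequence through the engine
#'
#' Drives a session from root to completion: gates are acknowledged as they
#' are reached, and every question surfaced as manual is answered from
#' `answers`. Questions auto-answered from the patient record consume no
#' entry. Errors if a surfaced question has no answer provided.
#'
#' @param kb an `empirx_kb`.
#' @param patient an `empirx_patient`.
#' @param diagnosis working diagnosis.
#' @param answers data frame with columns `node`, `answer` (as produced by
#'   [enumerate_paths()]), or a named character vector keyed by node id.
#' @param at_time consultation timestamp.
#' @return a completed `empirx_session`.
#' @export
replay_answers <- function(kb, patient, diagnosis, answers,
                           at_time = Sys.time()) {
  if (is.character(answers))
    answers <- data.frame(node = names(answers), answer = unname(answers),
                          stringsAsFactors = FALSE)
  s <- start_session(kb, patient, diagnosis, at_time)
  guard <- 0L
  while (s$status == "in_progress") {
    guard <- guard + 1L
    if (guard > 1000L) stop("replay did not terminate")
    nd <- current_node(s)
    if (nd$kind == "gate") {
      s <- acknowledge_gate(s)
    } else {
      hit <- answers$answer[answers$node == nd$id]
      if (!length(hit))
        stop("no answer provided for question '", nd$id, "'")
      s <- submit_answer(s, hit[[1L]])
    }
  }
  s
}

consult_dose <- function(drug, why) {
  list(drug = drug, dose_amount = NA_real_, dose_unit = NA_character_,
       interval_hours = NA_real_, weight_used = NULL,
       consult = TRUE, rationale = why)
}

#' Select a dose from a drug's dose rule table
#'
#' Finds the unique eGFR band (half-open `[lo, hi)`) matching the patient,
#' skips pregnancy-disallowed rows, and resolves weight-based doses (basis
#' `"ideal"` via [ideal_body_weight()], `"actual"` via recorded weight; the
#' returned amount is the total dose in mg, rounded to the nearest mg).
#' Returns a consult-marked decision when the table is renally banded and no
#' valid eGFR is available, when the matched row is an explicit consult row,
#' when pregnancy excludes the row, or when required anthropometrics are
#' missing.
#'
#' @param drug drug identifier with a dose table in `kb`.
#' @param kb an `empirx_kb`.
#' @param egfr numeric eGFR in mL/min/1.73m2, or `NULL` when absent/stale.
#' @param weight_ctx list with `weight_kg`, `height_cm`, `sex` as available.
#' @param pregnant logical.
#' @return a dose decision: list with `drug`, `dose_amount`, `dose_unit`,
#'   `interval_hours`, `weight_used`, `consult`, `rationale`.
#' @export
select_dose <- function(drug, kb, egfr = NULL, weight_ctx = list(),
                        pregnant = FALSE) {
  tb <- kb$dose_rules[[drug]]
  if (is.null(tb)) stop("no dose rule table for drug '", drug, "'")
  rows <- tb$rows
  renal <- nrow(rows) > 1L || rows$egfr_lo[1L] != 0 || is.finite(rows$egfr_hi[1L])
  if (renal && (is.null(egfr) || is.na(egfr)))
    return(consult_dose(drug, "no valid eGFR within 1 week"))
  i <- if (renal) which(rows$egfr_lo <= egfr & egfr < rows$egfr_hi) else 1L
  if (length(i) != 1L)
    return(consult_dose(drug, sprintf("no unique eGFR band for %g", egfr)))
  row <- rows[i, ]
  if (isTRUE(pregnant) && !row$pregnancy_allowed)
    return(consult_dose(drug, "row not allowed in pregnancy"))
  if (row$consult)
    return(consult_dose(drug, sprintf("eGFR band [%g,%g) requires specialist dosing",
                                      row$egfr_lo, row$egfr_hi)))
  weight_used <- NULL
  amount <- row$dose_amount
  unit <- row$dose_unit
  if (row$weight_basis == "ideal") {
    if (is.null(weight_ctx$height_cm) || is.na(weight_ctx$height_cm) ||
        is.null(weight_ctx$sex))
      return(consult_dose(drug, "height/sex required for ideal body weight"))
    kg <- ideal_body_weight(weight_ctx$sex, weight_ctx$height_cm)
    weight_used <- list(basis = "ideal", kg = kg)
    amount <- round(amount * kg)
    unit <- sub("/kg", "", unit, fixed = TRUE)
  } else if (row$weight_basis == "actual") {
    if (is.null(weight_ctx$weight_kg) || is.na(weight_ctx$weight_kg))
      return(consult_dose(drug, "actual body weight required"))
    weight_used <- list(basis = "actual", kg = weight_ctx$weight_kg)
    amount <- round(amount * weight_ctx$weight_kg)
    unit <- sub("/kg", "", unit, fixed = TRUE)
  }
  list(drug = drug, dose_amount = amount, dose_unit = unit,
       interval_hours = row$interval_hours, weight_used = weight_used,
       consult = FALSE,
       rationale = sprintf("eGFR band [%g,%g)", row$egfr_lo, row$egfr_hi))
}

regimen_conflicts <- function(reg, cultures, allergies,
                              trigger = "R") {
  drugs <- vapply(reg$drugs, function(d) d$drug, character(1))
  resistance <- any(vapply(cultures, function(cu) {
    ab <- cu$antibiogram
    length(ab) && any(names(ab) %in% drugs & ab %in% trigger)
  }, logical(1)))
  allergy <- nrow(allergies) > 0 &&
    any(vapply(drugs, function(d) any(allergy_hits_drug(allergies$drug_class, d)),
               logical(1)))
  c(resistance = resistance, allergy = allergy)
}

#' Deviate from the first-choice regimen for resistance or allergy
#'
#' If any culture in the (already windowed) history reports `R` for a
#' first-choice drug, or a recorded allergy matches a first-choice drug's
#' class, the first declared alternative free of both conflicts is chosen
#' (first fit, in declared order). If none exists the outcome is a referral
#' to the infectious disease specialist. Intermediate (`I`) results do not
#' trigger deviation unless `treat_intermediate_as_resistant` is set.
#'
#' @param regimen a regimen (from an advice node).
#' @param cultures culture list, already restricted by [cultures_in_window()].
#' @param allergies patient allergy data frame.
#' @param treat_intermediate_as_resistant logical, default `FALSE`.
#' @return list with `regimen` (the final regimen, or `NULL` for consult)
#'   and `deviation` (`NULL`, or list with `reason`, `from`, `to`).
#' @export
apply_deviation <- function(regimen, cultures, allergies,
                            treat_intermediate_as_resistant = FALSE) {
  trigger <- if (treat_intermediate_as_resistant) c("R", "I") else "R"
  c0 <- regimen_conflicts(regimen, cultures, allergies, trigger)
  if (!any(c0)) return(list(regimen = regimen, deviation = NULL))
  reason <- if (c0[["resistance"]]) "resistance" else "allergy"
  from <- vapply(regimen$drugs, function(d) d$drug, character(1))
  for (alt in regimen$alternatives) {
    if (!any(regimen_conflicts(alt, cultures, allergies, trigger))) {
      return(list(regimen = alt,
                  deviation = list(reason = reason, from = from,
                                   to = vapply(alt$drugs, function(d) d$drug,
                                               character(1)))))
    }
  }
  list(regimen = NULL,
       deviation = list(reason = reason, from = from, to = "consult"))
}

#' Generate the final antibiotic advice for a completed session
#'
#' Composes the terminal node's regimen with culture/allergy deviation and
#' per-drug dose selection into an advice outcome. Consult terminals pass
#' through unchanged. A deviation that exhausts all alternatives also yields
#' a consult outcome.
#'
#' @param session a completed `empirx_session`.
#' @return an `empirx_advice`: `kind` (`"regimen"` or `"consult"`),
#'   `drugs` (each with `drug`, `route`, `dose` decision), `duration_days`,
#'   `deviation`, `answer_trail`, `diagnosis`, `terminal`, `at_time`,
#'   `patient_id`.
#' @export
generate_advice <- function(session) {
  stopifnot(inherits(session, "empirx_session"))
  if (session$status != "complete")
    stop("session is not complete; current node is '", session$current_node,
         "' (", current_node(session)$kind, ")")
  nd <- current_node(session)
  p <- session$patient
  base <- list(diagnosis = session$diagnosis, terminal = nd$id,
               at_time = session$at_time, patient_id = p$patient_id,
               answer_trail = session$answer_trail)
  if (nd$consult) {
    return(structure(c(list(kind = "consult", drugs = list(),
                            duration_days = NA_real_, deviation = NULL), base),
                     class = "empirx_advice"))
  }
  cult <- cultures_in_window(p, session$at_time, 183)
  dev <- apply_deviation(nd$regimen, cult, p$allergies)
  if (is.null(dev$regimen)) {
    return(structure(c(list(kind = "consult", drugs = list(),
                            duration_days = NA_real_, deviation = dev$deviation),
                       base),
                     class = "empirx_advice"))
  }
  eg <- latest_valid_egfr(p, session$at_time)
  wctx <- list(weight_kg = p$weight_kg, height_cm = p$height_cm, sex = p$sex)
  drugs <- lapply(dev$regimen$drugs, function(d) {
    list(drug = d$drug, route = d$route,
         dose = select_dose(d$drug, session$kb,
                            egfr = if (is.null(eg)) NULL else eg$value,
                            weight_ctx = wctx,
                            pregnant = isTRUE(p$pregnant)))
  })
  structure(c(list(kind = "regimen", drugs = drugs,
                   duration_days = dev$regimen$duration_days,
                   deviation = dev$deviation), base),
            class = "empirx_advice")
}

#' @export
print.empirx_session <- function(x, ...) {
  cat(sprintf("Advisor session: %s for patient %s (%s)\n", x$diagnosis,
              x$patient$patient_id, x$status))
  nd <- current_node(x)
  if (x$status == "in_progress") {
    if (nd$kind == "question")
      cat(sprintf("  awaiting answer to '%s' [%s]\n", nd$prompt,
                  paste(names(nd$edges), collapse = "/")))
    else
      cat("  awaiting antibiogram review (gate '", nd$id, "')\n", sep = "")
  } else {
    cat("  terminal advice node: ", nd$id, "\n", sep = "")
  }
  if (nrow(x$answer_trail))
    cat(sprintf("  trail: %s\n",
                paste(sprintf("%s=%s(%s)", x$answer_trail$node,
                              x$answer_trail$answer,
                              substr(x$answer_trail$source, 1, 1)),
                      collapse = ", ")))
  invisible(x)
}

#' @export
print.empirx_advice <- function(x, ...) {
  cat("Antibiotic advice (", x$diagnosis, "):\n", sep = "")
  if (x$kind == "consult") {
    cat("  consult the infectious disease specialist\n")
  } else {
    for (d in x$drugs) {
      if (d$dose$consult)
        cat(sprintf("  %s %s — dose: consult specialist (%s)\n",
                    d$drug, d$route, d$dose$rationale))
      else
        cat(sprintf("  %s %s %g %s every %g h\n", d$drug, d$route,
                    d$dose$dose_amount, d$dose$dose_unit,
                    d$dose$interval_hours))
    }
    dur <- x$duration_days
    if (!all(is.na(dur)))
      cat("  duration: ", paste(dur, collapse = "-"), " days\n", sep = "")
  }
  if (!is.null(x$deviation))
    cat(sprintf("  deviation (%s): %s -> %s\n", x$deviation$reason,
                paste(x$deviation$from, collapse = "+"),
                paste(x$deviation$to, collapse = "+")))
  invisible(x)
}
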