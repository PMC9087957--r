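# Cohort and session serialization. Canonical format is JSON lines (one
# patient/session object per line); a CSV bundle directory (patients.csv,
# prescriptions.csv, cultures.csv, observations.csv) is accepted for
# cohorts. Schemas are documented in inst/extdata/cohort-schema.md.

patient_to_list <- function(p) {
  pres <- p$prescriptions
  list(
    patient_id = p$patient_id,
    birth_date = format(p$birth_date),
    sex = p$sex,
    ward = p$ward,
    admission_start = format_time(p$admission_start),
    admission_end = format_time(p$admission_end),
    weight_kg = p$weight_kg,
    height_cm = p$height_cm,
    pregnant = p$pregnant,
    diagnoses = as.list(p$diagnoses),
    allergies = lapply(seq_len(nrow(p$allergies)), function(i)
      list(drug_class = p$allergies$drug_class[i],
           ige_mediated = p$allergies$ige_mediated[i])),
    observations = lapply(seq_len(nrow(p$observations)), function(i)
      list(kind = p$observations$kind[i],
           value = p$observations$value[i],
           observed_at = format_time(p$observations$observed_at[i]))),
    cultures = lapply(p$cultures, function(cu)
      list(specimen = cu$specimen, collected_at = format_time(cu$collected_at),
           organism = cu$organism, antibiogram = as.list(cu$antibiogram))),
    prescriptions = lapply(seq_len(nrow(pres)), function(i)
      list(atc = pres$atc[i], drug = pres$drug[i],
           dose_amount = pres$dose_amount[i], dose_unit = pres$dose_unit[i],
           route = pres$route[i], interval_hours = pres$interval_hours[i],
           start = format_time(pres$start[i]), stop = format_time(pres$stop[i]),
           perioperative_context = pres$perioperative_context[i],
           other_indication = pres$other_indication[i],
           protocol_tag = pres$protocol_tag[i],
           splenectomy_date = if (is.na(pres$splenectomy_date[i])) NA_character_
                              else format(pres$splenectomy_date[i])))
  )
}

scalar_or_na <- function(x, as = as.character) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) return(as(NA))
  as(x)
}

patient_from_list <- function(x) {
  known <- c("patient_id", "birth_date", "sex", "ward", "admission_start",
             "admission_end", "weight_kg", "height_cm", "pregnant",
             "diagnoses", "allergies", "observations", "cultures",
             "prescriptions")
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown field(s) in patient record ",
         x$patient_id %||% "?", ": ", paste(extra, collapse = ", "))
  al <- if (length(x$allergies)) {
    data.frame(drug_class = vapply(x$allergies, function(a) a$drug_class, ""),
               ige_mediated = vapply(x$allergies, function(a) isTRUE(a$ige_mediated), NA),
               stringsAsFactors = FALSE)
  } else empty_allergies()
  ob <- if (length(x$observations)) {
    data.frame(kind = vapply(x$observations, function(o) o$kind, ""),
               value = vapply(x$observations, function(o) as.numeric(o$value), 0),
               observed_at = parse_time(vapply(x$observations, function(o) o$observed_at, "")),
               stringsAsFactors = FALSE)
  } else empty_observations()
  pr <- if (length(x$prescriptions)) {
    data.frame(
      atc = vapply(x$prescriptions, function(r) r$atc, ""),
      drug = vapply(x$prescriptions, function(r) r$drug, ""),
      dose_amount = vapply(x$prescriptions, function(r) scalar_or_na(r$dose_amount, as.numeric), 0),
      dose_unit = vapply(x$prescriptions, function(r) scalar_or_na(r$dose_unit), ""),
      route = vapply(x$prescriptions, function(r) r$route, ""),
      interval_hours = vapply(x$prescriptions, function(r) scalar_or_na(r$interval_hours, as.numeric), 0),
      start = parse_time(vapply(x$prescriptions, function(r) scalar_or_na(r$start), "")),
      stop = parse_time(vapply(x$prescriptions, function(r) scalar_or_na(r$stop), "")),
      perioperative_context = vapply(x$prescriptions, function(r) scalar_or_na(r$perioperative_context), ""),
      other_indication = vapply(x$prescriptions, function(r) scalar_or_na(r$other_indication, as.logical), NA),
      protocol_tag = vapply(x$prescriptions, function(r) scalar_or_na(r$protocol_tag), ""),
      splenectomy_date = parse_date(vapply(x$prescriptions, function(r) scalar_or_na(r$splenectomy_date), "")),
      stringsAsFactors = FALSE)
  } else empty_prescriptions()
  cu <- lapply(x$cultures %||% list(), function(c0)
    list(specimen = c0$specimen, collected_at = c0$collected_at,
         organism = c0$organism,
         antibiogram = unlist(c0$antibiogram)))
  new_patient(patient_id = x$patient_id, birth_date = x$birth_date,
              sex = x$sex, ward = x$ward,
              admission_start = x$admission_start,
              admission_end = x$admission_end,
              weight_kg = scalar_or_na(x$weight_kg, as.numeric),
              height_cm = scalar_or_na(x$height_cm, as.numeric),
              pregnant = scalar_or_na(x$pregnant, as.logical),
              allergies = al, observations = ob, cultures = cu,
              prescriptions = pr,
              diagnoses = unlist(x$diagnoses) %||% character())
}

#' Write a cohort to a JSON-lines file
#'
#' One patient object per line; deterministic output (fixed field order,
#' UTC ISO-8601 timestamps) so identical cohorts serialize byte-identically.
#'
#' @param cohort list of `empirx_patient` records.
#' @param path output file path (conventionally `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  lines <- vapply(cohort, function(p)
    as.character(jsonlite::toJSON(patient_to_list(p), auto_unbox = TRUE,
                                  digits = 8, null = "null", na = "null")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort extract
#'
#' Reads the canonical JSON-lines format (a file path) or a CSV bundle (a
#' directory containing `patients.csv`, `prescriptions.csv`, `cultures.csv`,
#' `observations.csv`). Unknown fields are rejected; malformed rows raise an
#' error naming the patient and field.
#'
#' @param source path to a `.jsonl` file or a CSV-bundle directory.
#' @return list of `empirx_patient` records.
#' @export
read_cohort <- function(source) {
  if (dir.exists(source)) return(read_cohort_csv(source))
  if (!file.exists(source)) stop("cohort file not found: ", source)
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln)
    patient_from_list(jsonlite::fromJSON(ln, simplifyVector = FALSE)))
}

read_cohort_csv <- function(dir) {
  need <- file.path(dir, c("patients.csv", "prescriptions.csv",
                           "cultures.csv", "observations.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("CSV bundle is missing: ", paste(basename(miss), collapse = ", "))
  pat <- utils::read.csv(need[1L], stringsAsFactors = FALSE)
  pre <- utils::read.csv(need[2L], stringsAsFactors = FALSE)
  cul <- utils::read.csv(need[3L], stringsAsFactors = FALSE)
  obs <- utils::read.csv(need[4L], stringsAsFactors = FALSE)
  blank_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  parse_semi <- function(s, f) if (is.na(s) || !nzchar(s)) NULL else
    lapply(strsplit(s, ";", fixed = TRUE)[[1L]], f)
  lapply(seq_len(nrow(pat)), function(i) {
    id <- as.character(pat$patient_id[i])
    al <- parse_semi(blank_na(pat$allergies[i]), function(tok) {
      kv <- strsplit(tok, ":", fixed = TRUE)[[1L]]
      list(drug_class = kv[1L], ige_mediated = identical(kv[2L], "ige"))
    })
    aldf <- if (is.null(al)) empty_allergies() else
      data.frame(drug_class = vapply(al, `[[`, "", "drug_class"),
                 ige_mediated = vapply(al, `[[`, NA, "ige_mediated"),
                 stringsAsFactors = FALSE)
    pri <- pre[pre$patient_id == id, , drop = FALSE]
    prdf <- if (!nrow(pri)) empty_prescriptions() else data.frame(
      atc = pri$atc, drug = pri$drug,
      dose_amount = as.numeric(pri$dose_amount),
      dose_unit = pri$dose_unit, route = pri$route,
      interval_hours = as.numeric(pri$interval_hours),
      start = parse_time(pri$start), stop = parse_time(blank_na(pri$stop)),
      perioperative_context = blank_na(pri$perioperative_context),
      other_indication = as.logical(pri$other_indication),
      protocol_tag = blank_na(pri$protocol_tag),
      splenectomy_date = as.Date(blank_na(pri$splenectomy_date)),
      stringsAsFactors = FALSE)
    obi <- obs[obs$patient_id == id, , drop = FALSE]
    obdf <- if (!nrow(obi)) empty_observations() else
      data.frame(kind = obi$kind, value = as.numeric(obi$value),
                 observed_at = parse_time(obi$observed_at),
                 stringsAsFactors = FALSE)
    cui <- cul[cul$patient_id == id, , drop = FALSE]
    cus <- lapply(seq_len(nrow(cui)), function(j) {
      ab <- parse_semi(blank_na(cui$antibiogram[j]), function(tok) {
        kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
        stats::setNames(kv[2L], kv[1L])
      })
      list(specimen = cui$specimen[j], collected_at = cui$collected_at[j],
           organism = cui$organism[j], antibiogram = unlist(ab))
    })
    new_patient(patient_id = id, birth_date = pat$birth_date[i],
                sex = pat$sex[i], ward = pat$ward[i],
                admission_start = pat$admission_start[i],
                admission_end = pat$admission_end[i],
                weight_kg = as.numeric(pat$weight_kg[i]),
                height_cm = as.numeric(pat$height_cm[i]),
                pregnant = as.logical(pat$pregnant[i]),
                allergies = aldf, observations = obdf, cultures = cus,
                prescriptions = prdf,
                diagnoses = if (is.na(blank_na(pat$diagnoses[i]))) character()
                            else strsplit(pat$diagnoses[i], ";", fixed = TRUE)[[1L]])
  })
}

advice_to_list <- function(a) {
  if (is.null(a)) return(NULL)
  list(kind = a$kind, diagnosis = a$diagnosis, terminal = a$terminal,
       at_time = format_time(a$at_time),
       duration_days = a$duration_days,
       drugs = lapply(a$drugs, function(d)
         list(drug = d$drug, route = d$route,
              dose_amount = d$dose$dose_amount, dose_unit = d$dose$dose_unit,
              interval_hours = d$dose$interval_hours,
              dose_consult = d$dose$consult)),
       deviation = a$deviation,
       answer_trail = lapply(seq_len(nrow(a$answer_trail)), function(i)
         as.list(a$answer_trail[i, ])))
}

advice_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  tr <- if (length(x$answer_trail)) {
    data.frame(node = vapply(x$answer_trail, `[[`, "", "node"),
               answer = vapply(x$answer_trail, `[[`, "", "answer"),
               source = vapply(x$answer_trail, `[[`, "", "source"),
               stringsAsFactors = FALSE)
  } else data.frame(node = character(), answer = character(),
                    source = character(), stringsAsFactors = FALSE)
  structure(list(
    kind = x$kind, diagnosis = x$diagnosis, terminal = x$terminal,
    at_time = parse_time(x$at_time),
    duration_days = as.numeric(unlist(x$duration_days) %||% NA_real_),
    drugs = lapply(x$drugs, function(d)
      list(drug = d$drug, route = d$route,
           dose = list(drug = d$drug,
                       dose_amount = scalar_or_na(d$dose_amount, as.numeric),
                       dose_unit = scalar_or_na(d$dose_unit),
                       interval_hours = scalar_or_na(d$interval_hours, as.numeric),
                       weight_used = NULL,
                       consult = isTRUE(d$dose_consult),
                       rationale = "(deserialized)"))),
    deviation = x$deviation,
    answer_trail = tr), class = "empirx_advice")
}

#' Write CDSS sessions to a JSON-lines file
#'
#' @param sessions list of session records as produced by [generate_cohort()]:
#'   each a list with `session_id`, `patient_id`, `diagnosis`, `at_time`,
#'   `is_test` and `advice` (an `empirx_advice` or `NULL`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  lines <- vapply(sessions, function(s)
    as.character(jsonlite::toJSON(
      list(session_id = s$session_id, patient_id = s$patient_id,
           diagnosis = s$diagnosis, at_time = format_time(parse_time(s$at_time)),
           is_test = isTRUE(s$is_test), advice = advice_to_list(s$advice)),
      auto_unbox = TRUE, digits = 8, null = "null", na = "null")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read CDSS sessions from a JSON-lines file
#'
#' @param path path to a sessions `.jsonl` file.
#' @return list of session records.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("sessions file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    list(session_id = x$session_id, patient_id = x$patient_id,
         diagnosis = x$diagnosis, at_time = parse_time(x$at_time),
         is_test = isTRUE(x$is_test), advice = advice_from_list(x$advice))
  })
}
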