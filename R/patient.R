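# Patient / cohort data model and the data-binding freshness rules:
# cultures are presented from the previous 6 months (183 days) only, and an
# eGFR auto-answers dosing only if determined strictly less than 1 week
# (7 x 24 h) before the moment the CDSS is consulted.

empty_allergies <- function()
  data.frame(drug_class = character(), ige_mediated = logical(),
             stringsAsFactors = FALSE)

empty_observations <- function()
  data.frame(kind = character(), value = numeric(),
             observed_at = as.POSIXct(character(), tz = "UTC"),
             stringsAsFactors = FALSE)

empty_prescriptions <- function()
  data.frame(atc = character(), drug = character(),
             dose_amount = numeric(), dose_unit = character(),
             route = character(), interval_hours = numeric(),
             start = as.POSIXct(character(), tz = "UTC"),
             stop = as.POSIXct(character(), tz = "UTC"),
             perioperative_context = character(),
             other_indication = logical(),
             protocol_tag = character(),
             splenectomy_date = as.Date(character()),
             stringsAsFactors = FALSE)

#' Construct a patient record
#'
#' The in-memory form of one EHR-extract row bundle: demographics and
#' admission, optional weight/height/pregnancy, recorded allergies,
#' observations (eGFR in mL/min/1.73m2, absolute neutrophils in 1e9/L),
#' culture results with antibiograms, prescriptions, and diagnosis labels
#' (ground truth used by the stewardship evaluation only, never by the
#' advisor engine).
#'
#' @param patient_id opaque identifier.
#' @param birth_date Date (or parseable string).
#' @param sex `"male"` or `"female"`.
#' @param ward admission ward label (the stratification variable).
#' @param admission_start,admission_end admission interval (UTC timestamps).
#' @param weight_kg,height_cm optional anthropometrics.
#' @param pregnant logical or `NA` (unknown; the engine then asks).
#' @param allergies data frame with columns `drug_class`, `ige_mediated`.
#' @param observations data frame with columns `kind` (`"egfr"` or
#'   `"neutrophils"`), `value`, `observed_at`.
#' @param cultures list of culture results: each a list with `specimen`,
#'   `collected_at`, `organism`, `antibiogram` (named character vector of
#'   `"S"`/`"I"`/`"R"` keyed by drug).
#' @param prescriptions data frame, see [read_cohort()] schema.
#' @param diagnoses character vector of diagnosis labels.
#' @return an object of class `empirx_patient`.
#' @export
new_patient <- function(patient_id, birth_date, sex, ward,
                        admission_start, admission_end,
                        weight_kg = NA_real_, height_cm = NA_real_,
                        pregnant = NA,
                        allergies = empty_allergies(),
                        observations = empty_observations(),
                        cultures = list(),
                        prescriptions = empty_prescriptions(),
                        diagnoses = character()) {
  sex <- match.arg(sex, c("male", "female"))
  admission_start <- parse_time(admission_start)
  admission_end <- parse_time(admission_end)
  if (is.na(admission_start) || is.na(admission_end))
    stop("patient ", patient_id, ": admission timestamps are required")
  if (admission_end < admission_start)
    stop("patient ", patient_id, ": admission_end precedes admission_start")
  observations$observed_at <- parse_time(observations$observed_at)
  if (nrow(observations) && any(observations$value < 0, na.rm = TRUE))
    stop("patient ", patient_id, ": negative observation value")
  prescriptions$start <- parse_time(prescriptions$start)
  prescriptions$stop <- parse_time(prescriptions$stop)
  bad <- !is.na(prescriptions$stop) & !is.na(prescriptions$start) &
    prescriptions$stop < prescriptions$start
  if (any(bad))
    stop("patient ", patient_id, ": prescription stop precedes start (row ",
         which(bad)[1L], ", drug ", prescriptions$drug[which(bad)[1L]], ")")
  cultures <- lapply(cultures, function(cu) {
    cu$collected_at <- parse_time(cu$collected_at)
    if (!is.null(cu$organism) && !is.na(cu$organism) && nzchar(cu$organism) &&
        !length(cu$antibiogram))
      stop("patient ", patient_id, ": culture with organism but empty antibiogram")
    cu
  })
  structure(list(patient_id = as.character(patient_id),
                 birth_date = parse_date(birth_date),
                 sex = sex, ward = as.character(ward),
                 admission_start = admission_start,
                 admission_end = admission_end,
                 weight_kg = as.numeric(weight_kg),
                 height_cm = as.numeric(height_cm),
                 pregnant = as.logical(pregnant),
                 allergies = allergies,
                 observations = observations,
                 cultures = cultures,
                 prescriptions = prescriptions,
                 diagnoses = as.character(diagnoses)),
            class = "empirx_patient")
}

#' @export
print.empirx_patient <- function(x, ...) {
  cat(sprintf("Patient %s: %s, born %s, ward %s\n", x$patient_id, x$sex,
              format(x$birth_date), x$ward))
  cat(sprintf("  admitted %s .. %s\n", format_time(x$admission_start),
              format_time(x$admission_end)))
  cat(sprintf("  %d prescription(s), %d culture(s), %d observation(s)\n",
              nrow(x$prescriptions), length(x$cultures), nrow(x$observations)))
  invisible(x)
}

#' Age in whole years at a given time
#'
#' @param patient an `empirx_patient`.
#' @param at timestamp (defaults to admission start).
#' @return integer age in completed years.
#' @export
patient_age <- function(patient, at = patient$admission_start) {
  floor(as.numeric(difftime(parse_time(at), as.POSIXct(patient$birth_date, tz = "UTC"),
                            units = "days")) / 365.25)
}

#' Is an ATC code a systemic antibacterial?
#'
#' True iff the code starts with `"J01"` (antibacterials for systemic use);
#' the comparison is case-sensitive.
#'
#' @param atc character vector of ATC codes.
#' @return logical vector.
#' @export
#' @examples
#' is_systemic_antibacterial(c("J01CA04", "J02AC01"))
is_systemic_antibacterial <- function(atc) {
  stopifnot(is.character(atc), all(nzchar(atc)))
  startsWith(atc, "J01")
}

#' Most recent valid eGFR observation
#'
#' Returns the most recent eGFR observation made at or before `at_time` and
#' strictly less than 7 days old; `NULL` otherwise (the engine then falls
#' back to manual input / a consult dose decision).
#'
#' @param patient an `empirx_patient`.
#' @param at_time timestamp at which the CDSS is consulted.
#' @return a list with `kind`, `value`, `observed_at`, or `NULL`.
#' @export
latest_valid_egfr <- function(patient, at_time) {
  at_time <- parse_time(at_time)
  obs <- patient$observations
  obs <- obs[obs$kind == "egfr" & !is.na(obs$observed_at) &
               obs$observed_at <= at_time &
               as.numeric(difftime(at_time, obs$observed_at, units = "secs")) <
                 7 * 86400, , drop = FALSE]
  if (!nrow(obs)) return(NULL)
  i <- which.max(obs$observed_at)
  list(kind = "egfr", value = obs$value[i], observed_at = obs$observed_at[i])
}

#' Culture results within the presentation window
#'
#' Cultures collected in the `window_days` days up to and including
#' `at_time`, newest first. The default window of 183 days implements the
#' 6-month culture-history rule.
#'
#' @param patient an `empirx_patient`.
#' @param at_time timestamp at which the CDSS is consulted.
#' @param window_days positive number of days to look back.
#' @return list of culture results, sorted by `collected_at` descending.
#' @export
cultures_in_window <- function(patient, at_time, window_days = 183) {
  stopifnot(window_days > 0)
  at_time <- parse_time(at_time)
  lo <- at_time - window_days * 86400
  keep <- Filter(function(cu) {
    !is.na(cu$collected_at) && cu$collected_at <= at_time && cu$collected_at >= lo
  }, patient$cultures)
  if (!length(keep)) return(list())
  ord <- order(vapply(keep, function(cu) as.numeric(cu$collected_at), numeric(1)),
               decreasing = TRUE)
  keep[ord]
}
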