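# Stewardship evaluation: cohort filtering, prophylaxis classification,
# adherence classification against CDSS advice, proportional stratified
# sampling for the eligibility estimate, and the evaluation report
# (eligibility % with Wald CI, extrapolated eligible count, usage rate,
# adherence rates, per-diagnosis/per-ward usage).

#' Filter a cohort to the evaluable population
#'
#' Keeps adult patients (age >= 18 at admission) admitted for more than one
#' day (strictly > 24 h) with at least one systemic antibacterial (ATC
#' `J01...`) prescription of which at least one is not prophylactic.
#'
#' @param cohort list of `empirx_patient` records.
#' @return the included subset of `cohort`.
#' @export
filter_cohort <- function(cohort) {
  Filter(function(p) {
    if (patient_age(p) < 18) return(FALSE)
    span_h <- as.numeric(difftime(p$admission_end, p$admission_start,
                                  units = "hours"))
    if (span_h <= 24) return(FALSE)
    pres <- p$prescriptions
    if (!nrow(pres)) return(FALSE)
    j01 <- is_systemic_antibacterial(pres$atc)
    if (!any(j01)) return(FALSE)
    any(vapply(which(j01), function(i)
      !classify_prophylaxis(pres[i, ], p)$is_prophylaxis, logical(1)))
  }, cohort)
}

#' Classify a prescription as prophylaxis or therapy
#'
#' Applies the prophylaxis definitions in fixed order and returns the first
#' matching rule: any course shorter than 48 h; cotrimoxazole at a dose of
#' 480 mg; cefazolin started peri-operatively without another clear
#' indication (an explicit boolean input, not inferred); the protocol tags
#' SDD, neutropenia and COPD; and pheneticillin started within 2 years
#' (730 days) after splenectomy.
#'
#' @param prescription a one-row prescription data frame or equivalent list.
#' @param patient the owning `empirx_patient` (reserved for future rules;
#'   current rules read the prescription only).
#' @return list with `rule` (one of `duration_lt_48h`, `cotrimoxazole_480`,
#'   `perioperative_cefazolin`, `sdd`, `neutropenia`, `copd`,
#'   `pheneticillin_post_splenectomy`, `none`) and `is_prophylaxis`.
#' @export
classify_prophylaxis <- function(prescription, patient = NULL) {
  pr <- as.list(prescription)
  g <- function(f) {
    v <- pr[[f]]
    if (is.null(v) || length(v) != 1L) NA else v
  }
  start <- parse_time(g("start"))
  stop_ <- parse_time(g("stop"))
  dur_h <- if (!is.na(start) && !is.na(stop_))
    as.numeric(difftime(stop_, start, units = "hours")) else NA_real_
  drug <- g("drug")
  tag <- g("protocol_tag")
  rule <- if (!is.na(dur_h) && dur_h < 48) {
    "duration_lt_48h"
  } else if (identical(drug, "cotrimoxazole") &&
             identical(to_mg(g("dose_amount"), g("dose_unit")), 480)) {
    "cotrimoxazole_480"
  } else if (identical(drug, "cefazolin") &&
             isTRUE(g("perioperative_context") %in% c("pre", "intra", "post")) &&
             !isTRUE(g("other_indication"))) {
    "perioperative_cefazolin"
  } else if (identical(tag, "sdd")) {
    "sdd"
  } else if (identical(tag, "neutropenia")) {
    "neutropenia"
  } else if (identical(tag, "copd")) {
    "copd"
  } else if (identical(drug, "pheneticillin") &&
             !is.na(g("splenectomy_date")) && !is.na(start) &&
             {
               d <- as.numeric(difftime(start,
                                        as.POSIXct(parse_date(g("splenectomy_date")),
                                                   tz = "UTC"),
                                        units = "days"))
               d >= 0 && d <= 730
             }) {
    "pheneticillin_post_splenectomy"
  } else {
    "none"
  }
  list(rule = rule, is_prophylaxis = rule != "none")
}

#' Classify prescriptions' adherence to a CDSS advice
#'
#' Chart-review rule, made deterministic: only prescriptions starting
#' within `window_hours` after the advice are considered. `complete` means
#' every advised drug was prescribed with matching route and dosage regimen
#' (dose after mg/g normalization, and dosing interval when the advice
#' specifies one); `partial` means at least one advised drug was prescribed
#' but the set is a proper subset or a route/dosage regimen differs;
#' `none` means no advised drug was prescribed.
#'
#' @param advice an `empirx_advice` with `kind = "regimen"` (consult
#'   advices are not classifiable and raise an error).
#' @param prescriptions a prescription data frame (typically
#'   `patient$prescriptions`).
#' @param advised_at timestamp of the advice; defaults to `advice$at_time`.
#' @param window_hours matching window after the advice, default 24.
#' @return an `empirx_adherence`: list with `category` (`complete`,
#'   `partial` or `none`) and `detail` (per-drug match table).
#' @export
classify_adherence <- function(advice, prescriptions,
                               advised_at = NULL, window_hours = 24) {
  stopifnot(inherits(advice, "empirx_advice"))
  if (advice$kind != "regimen")
    stop("a consult advice has no drug regimen to classify")
  advised_at <- parse_time(advised_at %||% advice$at_time)
  pres <- prescriptions
  if (nrow(pres)) {
    keep <- !is.na(pres$start) & pres$start >= advised_at &
      pres$start <= advised_at + window_hours * 3600
    pres <- pres[keep, , drop = FALSE]
  }
  detail <- do.call(rbind, lapply(advice$drugs, function(d) {
    rows <- pres[pres$drug == d$drug, , drop = FALSE]
    prescribed <- nrow(rows) > 0
    route_ok <- prescribed && any(rows$route == d$route)
    reg_ok <- FALSE
    full_ok <- FALSE
    if (prescribed) {
      adv_mg <- to_mg(d$dose$dose_amount, d$dose$dose_unit)
      match_row <- function(i) {
        if (d$dose$consult) return(TRUE)  # no concrete regimen to contradict
        pre_mg <- to_mg(rows$dose_amount[i], rows$dose_unit[i])
        dose_ok <- if (!is.na(adv_mg) && !is.na(pre_mg)) {
          isTRUE(all.equal(adv_mg, pre_mg))
        } else {
          identical(rows$dose_unit[i], d$dose$dose_unit) &&
            isTRUE(all.equal(rows$dose_amount[i], d$dose$dose_amount))
        }
        int_ok <- is.na(d$dose$interval_hours) ||
          (!is.na(rows$interval_hours[i]) &&
             rows$interval_hours[i] == d$dose$interval_hours)
        dose_ok && int_ok
      }
      regs <- vapply(seq_len(nrow(rows)), match_row, logical(1))
      reg_ok <- any(regs)
      full_ok <- any(regs & rows$route == d$route)
    }
    data.frame(drug = d$drug, advised_route = d$route,
               prescribed = prescribed, route_match = route_ok,
               regimen_match = reg_ok, full_match = full_ok,
               stringsAsFactors = FALSE)
  }))
  category <- if (!any(detail$prescribed)) "none"
    else if (all(detail$full_match)) "complete"
    else "partial"
  structure(list(category = category, detail = detail),
            class = "empirx_adherence")
}

#' @export
print.empirx_adherence <- function(x, ...) {
  cat("Adherence:", x$category, "\n")
  print(x$detail)
  invisible(x)
}

#' Proportional stratified random sample
#'
#' Per-stratum sample sizes are proportional to stratum sizes with
#' largest-remainder rounding (summing exactly to `n`; remainder ties are
#' broken by stratum name for determinism, and allocations never exceed the
#' stratum size). Sampling within strata is uniform without replacement.
#'
#' @param cohort list of `empirx_patient` records.
#' @param n total sample size, `<= length(cohort)`.
#' @param stratum patient field to stratify on, default `"ward"`.
#' @param seed integer seed making the draw reproducible.
#' @return subset of `cohort`; the per-stratum allocation is attached as
#'   attribute `"stratum_counts"`.
#' @export
proportional_stratified_sample <- function(cohort, n, stratum = "ward",
                                           seed = NULL) {
  if (n > length(cohort))
    stop("sample size ", n, " exceeds cohort size ", length(cohort))
  labels <- vapply(cohort, function(p) as.character(p[[stratum]]), character(1))
  sizes <- table(labels)
  sizes <- sizes[order(names(sizes))]
  exact <- n * as.numeric(sizes) / sum(sizes)
  alloc <- floor(exact)
  rem <- exact - alloc
  short <- n - sum(alloc)
  if (short > 0) {
    ord <- order(-rem, names(sizes))
    take <- ord[seq_len(short)]
    alloc[take] <- alloc[take] + 1
  }
  # cap at stratum size, pushing any excess to strata with spare capacity
  repeat {
    over <- alloc > as.numeric(sizes)
    if (!any(over)) break
    excess <- sum(alloc[over] - as.numeric(sizes)[over])
    alloc[over] <- as.numeric(sizes)[over]
    cap <- as.numeric(sizes) - alloc
    ord <- order(-rem, names(sizes))
    for (i in ord) {
      if (excess == 0) break
      add <- min(cap[i], excess)
      alloc[i] <- alloc[i] + add
      excess <- excess - add
    }
  }
  idx <- with_seed(seed, {
    unlist(lapply(seq_along(sizes), function(i) {
      pool <- which(labels == names(sizes)[i])
      pool[sample.int(length(pool), alloc[i])]
    }))
  })
  idx <- sort(idx)
  out <- cohort[idx]
  attr(out, "stratum_counts") <- stats::setNames(as.integer(alloc), names(sizes))
  out
}

#' Binomial proportion with Wald confidence interval
#'
#' Point estimate `100 k / n` per cent and the normal-approximation (Wald)
#' interval `100 (p +- z sqrt(p(1-p)/n))`, clipped to `[0, 100]`.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `> 0`.
#' @param level confidence level, default 0.95.
#' @return list with `point`, `lower`, `upper` (all in per cent), `k`, `n`.
#' @export
#' @examples
#' proportion_ci(100, 248)
proportion_ci <- function(k, n, level = 0.95) {
  if (n <= 0) stop("proportion_ci: n must be positive")
  if (k < 0 || k > n) stop("proportion_ci: k must be in [0, n]")
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  list(point = 100 * p,
       lower = max(0, 100 * (p - z * se)),
       upper = min(100, 100 * (p + z * se)),
       k = k, n = n)
}

#' Extrapolated count of CDSS-eligible patients
#'
#' The sample proportion is rounded to three decimals before scaling and
#' the product is floored, reproducing the published arithmetic
#' (`floor(3349 * 0.403) = 1349`).
#'
#' @param n_cohort cohort size to extrapolate to.
#' @param k,n eligible count and size of the stratified sample.
#' @return integer extrapolated count.
#' @export
#' @examples
#' extrapolate_eligible(3349, 100, 248)
extrapolate_eligible <- function(n_cohort, k, n) {
  as.integer(floor(n_cohort * round(k / n, 3)))
}

#' CDSS usage rate
#'
#' Real (non-test) sessions as a percentage of the extrapolated eligible
#' population, truncated to one decimal.
#'
#' @param n_sessions total number of CDSS sessions.
#' @param n_test number of test/try-out sessions among them.
#' @param n_eligible extrapolated number of eligible patients.
#' @return usage rate in per cent (one decimal, truncated).
#' @export
#' @examples
#' usage_rate_pct(184, 15, 1349)
usage_rate_pct <- function(n_sessions, n_test, n_eligible) {
  if (n_eligible <= 0) return(0)
  trunc1(100 * (n_sessions - n_test) / n_eligible)
}

#' Percentage of advices followed completely or partly
#'
#' @param n_complete,n_partial adherence counts.
#' @param n_used number of real CDSS uses (advice or consult outcome).
#' @return followed rate in per cent (one decimal, truncated).
#' @export
#' @examples
#' followed_rate_pct(91, 23, 169)
followed_rate_pct <- function(n_complete, n_partial, n_used) {
  if (n_used <= 0) return(0)
  trunc1(100 * (n_complete + n_partial) / n_used)
}

#' Evaluate CDSS eligibility, usage and adherence on a cohort
#'
#' Implements the stewardship evaluation: filter the cohort to the
#' evaluable population, estimate the proportion with a CDSS-included
#' diagnosis from a proportional stratified sample (with Wald CI),
#' extrapolate the eligible count, compute the usage rate from the session
#' log (excluding test sessions), and classify adherence of each really
#' advised patient's prescriptions within a 24-hour window. The adherence
#' denominator is all real uses, so consult advices count towards `none`.
#'
#' @param cohort list of `empirx_patient` records (unfiltered; filtering is
#'   applied internally unless `prefilter = FALSE`).
#' @param sessions list of session records (see [read_sessions()]).
#' @param sample_n stratified sample size (248 in the evaluation design).
#' @param seed seed for the sample draw.
#' @param eligible_diagnoses diagnosis labels counted as CDSS-eligible.
#' @param window_hours adherence matching window, default 24.
#' @param prefilter apply [filter_cohort()] first (default `TRUE`).
#' @return an `empirx_eval_report`.
#' @export
evaluate <- function(cohort, sessions, sample_n, seed = NULL,
                     eligible_diagnoses = cdss_diagnoses(),
                     window_hours = 24, prefilter = TRUE) {
  if (!length(cohort)) stop("evaluate: empty cohort")
  inc <- if (prefilter) filter_cohort(cohort) else cohort
  if (!length(inc)) stop("evaluate: no patients left after filtering")
  n_cohort <- length(inc)
  samp <- proportional_stratified_sample(inc, sample_n, seed = seed)
  k <- sum(vapply(samp, function(p) any(p$diagnoses %in% eligible_diagnoses),
                  logical(1)))
  ci <- proportion_ci(k, sample_n)
  n_eligible <- extrapolate_eligible(n_cohort, k, sample_n)

  n_total <- length(sessions)
  is_test <- vapply(sessions, function(s) isTRUE(s$is_test), logical(1))
  n_test <- sum(is_test)
  real <- sessions[!is_test]
  n_real <- length(real)

  by_id <- stats::setNames(cohort, vapply(cohort, `[[`, "", "patient_id"))
  n_advice <- 0L; n_consult <- 0L; n_complete <- 0L; n_partial <- 0L
  for (s in real) {
    a <- s$advice
    if (is.null(a)) next
    if (a$kind == "consult") {
      n_consult <- n_consult + 1L
    } else {
      n_advice <- n_advice + 1L
      p <- by_id[[s$patient_id]]
      if (!is.null(p)) {
        cl <- classify_adherence(a, p$prescriptions,
                                 advised_at = s$at_time,
                                 window_hours = window_hours)
        if (cl$category == "complete") n_complete <- n_complete + 1L
        if (cl$category == "partial") n_partial <- n_partial + 1L
      }
    }
  }
  n_none <- n_real - n_complete - n_partial

  dx <- table(vapply(real, function(s) s$diagnosis %||% NA_character_,
                     character(1)))
  ward <- table(vapply(real, function(s) {
    p <- by_id[[s$patient_id]]
    if (is.null(p)) NA_character_ else p$ward
  }, character(1)))

  structure(list(
    n_cohort = n_cohort, n_sample = sample_n, k_eligible = k,
    eligibility = ci,
    n_eligible_extrapolated = n_eligible,
    n_sessions_total = n_total, n_sessions_test = n_test,
    usage_rate = usage_rate_pct(n_total, n_test, n_eligible),
    n_used = n_real, n_advice = n_advice, n_consult_advice = n_consult,
    adherence = list(complete = n_complete, partial = n_partial,
                     none = n_none),
    adherence_rate = followed_rate_pct(n_complete, n_partial, n_real),
    usage_by_diagnosis = dx, usage_by_ward = ward),
    class = "empirx_eval_report")
}

#' @export
print.empirx_eval_report <- function(x, ...) {
  cat("CDSS stewardship evaluation\n")
  cat(sprintf("  evaluable cohort:            %d patients\n", x$n_cohort))
  cat(sprintf("  stratified sample:           %d eligible of %d = %.1f%% (95%% CI %.1f-%.1f)\n",
              x$k_eligible, x$n_sample, x$eligibility$point,
              x$eligibility$lower, x$eligibility$upper))
  cat(sprintf("  extrapolated eligible:       %d patients\n",
              x$n_eligible_extrapolated))
  cat(sprintf("  CDSS sessions:               %d (%d test) -> usage %.1f%%\n",
              x$n_sessions_total, x$n_sessions_test, x$usage_rate))
  cat(sprintf("  real uses:                   %d (%d advice, %d consult)\n",
              x$n_used, x$n_advice, x$n_consult_advice))
  cat(sprintf("  followed: %d complete + %d partial of %d = %.1f%% (not followed: %d)\n",
              x$adherence$complete, x$adherence$partial, x$n_used,
              x$adherence_rate, x$adherence$none))
  if (length(x$usage_by_diagnosis)) {
    cat("  uses by diagnosis:\n")
    for (d in names(sort(x$usage_by_diagnosis, decreasing = TRUE)))
      cat(sprintf("    %-28s %d\n", d, x$usage_by_diagnosis[[d]]))
  }
  invisible(x)
}
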