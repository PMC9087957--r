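test_that("cohort filtering keeps adults, >1-day admissions, and non-prophylactic J01 use", {
  # only a 36-h perioperative cefazolin course: prophylaxis-only, excluded
  proph <- make_patient(patient_id = "A", prescriptions = make_rx(
    drug = "cefazolin", atc = "J01DB04", dose_amount = 1000, route = "iv",
    start = T0, stop = T0 + 36 * 3600, perioperative_context = "intra"))
  # therapeutic amoxicillin but a 1-day admission: excluded
  oneday <- make_patient(patient_id = "B",
                         admission_start = "2017-01-10 08:00:00",
                         admission_end = "2017-01-11 04:00:00")
  # adult, 10-day admission, 7-day ciprofloxacin course: included
  ok <- make_patient(patient_id = "C", prescriptions = make_rx(
    drug = "ciprofloxacin", atc = "J01MA02", dose_amount = 400, route = "iv",
    start = T0, stop = T0 + 7 * 86400))
  # minor: excluded
  minor <- make_patient(patient_id = "D", birth_date = "2001-06-01",
                        prescriptions = make_rx(start = T0, stop = T0 + 5 * 86400))
  # no J01 at all: excluded
  noj01 <- make_patient(patient_id = "E", prescriptions = make_rx(
    drug = "paracetamol", atc = "N02BE01", start = T0, stop = T0 + 5 * 86400))
  oneday$prescriptions <- make_rx(start = oneday$admission_start,
                                  stop = oneday$admission_start + 5 * 86400)
  kept <- filter_cohort(list(proph, oneday, ok, minor, noj01))
  expect_equal(vapply(kept, `[[`, "", "patient_id"), "C")
})

test_that("prophylaxis rules match in their documented order", {
  rx <- function(...) as.list(make_rx(...))
  # any J01 course under 48 h
  r <- classify_prophylaxis(rx(drug = "amoxicillin", stop = T0 + 38 * 3600,
                               start = T0))
  expect_equal(r$rule, "duration_lt_48h"); expect_true(r$is_prophylaxis)
  expect_equal(classify_prophylaxis(rx(start = T0, stop = T0 + 48 * 3600))$rule,
               "none")
  # cotrimoxazole 480 mg regardless of duration, including unit-normalized
  expect_equal(classify_prophylaxis(rx(drug = "cotrimoxazole",
                                       dose_amount = 480, dose_unit = "mg",
                                       start = T0, stop = T0 + 10 * 86400))$rule,
               "cotrimoxazole_480")
  expect_equal(classify_prophylaxis(rx(drug = "cotrimoxazole",
                                       dose_amount = 0.48, dose_unit = "g",
                                       start = T0, stop = T0 + 10 * 86400))$rule,
               "cotrimoxazole_480")
  expect_equal(classify_prophylaxis(rx(drug = "cotrimoxazole",
                                       dose_amount = 960, dose_unit = "mg",
                                       start = T0, stop = T0 + 10 * 86400))$rule,
               "none")
  # perioperative cefazolin without another clear indication
  expect_equal(classify_prophylaxis(rx(drug = "cefazolin",
                                       perioperative_context = "post",
                                       start = T0, stop = T0 + 4 * 86400))$rule,
               "perioperative_cefazolin")
  expect_equal(classify_prophylaxis(rx(drug = "cefazolin",
                                       perioperative_context = "post",
                                       other_indication = TRUE,
                                       start = T0, stop = T0 + 4 * 86400))$rule,
               "none")
  # protocol tags
  for (tag in c("sdd", "neutropenia", "copd"))
    expect_equal(classify_prophylaxis(rx(protocol_tag = tag, start = T0,
                                         stop = T0 + 7 * 86400))$rule, tag)
  # pheneticillin within two years of splenectomy
  expect_equal(classify_prophylaxis(rx(drug = "pheneticillin",
                                       splenectomy_date = as.Date(T0) - 365,
                                       start = T0, stop = T0 + 7 * 86400))$rule,
               "pheneticillin_post_splenectomy")
  expect_equal(classify_prophylaxis(rx(drug = "pheneticillin",
                                       splenectomy_date = as.Date(T0) - 3 * 365,
                                       start = T0, stop = T0 + 7 * 86400))$rule,
               "none")
})

adv_fixture <- function(drugs) {
  structure(list(kind = "regimen", diagnosis = "sepsis", terminal = "adv",
                 at_time = T0, patient_id = "X",
                 duration_days = 7,
                 drugs = lapply(drugs, function(d)
                   list(drug = d[[1]], route = d[[2]],
                        dose = list(drug = d[[1]], dose_amount = d[[3]],
                                    dose_unit = "mg", interval_hours = d[[4]],
                                    weight_used = NULL, consult = FALSE,
                                    rationale = "fixture"))),
                 deviation = NULL,
                 answer_trail = data.frame(node = character(),
                                           answer = character(),
                                           source = character())),
            class = "empirx_advice")
}

test_that("adherence is complete/partial/none per the chart-review definitions", {
  adv <- adv_fixture(list(list("piperacillin-tazobactam", "iv", 4000, 8)))
  rx_exact <- make_rx(drug = "piperacillin-tazobactam", atc = "J01CR05",
                      dose_amount = 4000, route = "iv", interval_hours = 8)
  expect_equal(classify_adherence(adv, rx_exact)$category, "complete")
  # different route or dosage regimen -> partly followed
  expect_equal(classify_adherence(adv, make_rx(
    drug = "piperacillin-tazobactam", dose_amount = 4000, route = "oral",
    interval_hours = 8))$category, "partial")
  expect_equal(classify_adherence(adv, make_rx(
    drug = "piperacillin-tazobactam", dose_amount = 2000, route = "iv",
    interval_hours = 8))$category, "partial")
  expect_equal(classify_adherence(adv, make_rx(
    drug = "piperacillin-tazobactam", dose_amount = 4000, route = "iv",
    interval_hours = 12))$category, "partial")
  # g/mg normalization: 4 g == 4000 mg
  expect_equal(classify_adherence(adv, make_rx(
    drug = "piperacillin-tazobactam", dose_amount = 4, dose_unit = "g",
    route = "iv", interval_hours = 8))$category, "complete")
  # disjoint drug -> none
  expect_equal(classify_adherence(adv, make_rx(drug = "ciprofloxacin",
                                               route = "iv"))$category, "none")
  # outside the 24-h window -> none
  expect_equal(classify_adherence(adv, make_rx(
    drug = "piperacillin-tazobactam", dose_amount = 4000, route = "iv",
    interval_hours = 8, start = T0 + 30 * 3600))$category, "none")
  expect_equal(classify_adherence(adv, make_rx(
    drug = "piperacillin-tazobactam", dose_amount = 4000, route = "iv",
    interval_hours = 8, start = T0 - 3600))$category, "none")

  # one of two advised drugs -> partial
  adv2 <- adv_fixture(list(list("ceftriaxone", "iv", 2000, 24),
                           list("gentamicin", "iv", 400, 24)))
  expect_equal(classify_adherence(adv2, make_rx(
    drug = "ceftriaxone", dose_amount = 2000, route = "iv",
    interval_hours = 24))$category, "partial")

  # consult advice is not classifiable
  consult <- adv_fixture(list()); consult$kind <- "consult"
  expect_error(classify_adherence(consult, rx_exact), "consult")
})

test_that("adherence always yields exactly one category, consistent with its definition", {
  set.seed(77)
  drugs_pool <- list(list("ceftriaxone", "iv", 2000, 24),
                     list("gentamicin", "iv", 400, 24),
                     list("ciprofloxacin", "oral", 400, 12))
  for (i in 1:120) {
    adv <- adv_fixture(sample(drugs_pool, sample(1:2, 1)))
    n_rx <- sample(0:3, 1)
    rx <- if (n_rx == 0) empty_rx <- make_rx()[0, ] else
      do.call(rbind, lapply(seq_len(n_rx), function(j) {
        d <- sample(drugs_pool, 1)[[1]]
        make_rx(drug = d[[1]], dose_amount = sample(c(d[[3]], 999), 1),
                route = sample(c(d[[2]], "iv", "oral"), 1),
                interval_hours = sample(c(d[[4]], 6), 1),
                start = T0 + sample(c(2, 40), 1) * 3600)
      }))
    res <- classify_adherence(adv, rx)
    expect_true(res$category %in% c("complete", "partial", "none"))
    # re-derive the category from the detail table
    det <- res$detail
    want <- if (!any(det$prescribed)) "none"
            else if (all(det$full_match)) "complete" else "partial"
    expect_equal(res$category, want)
    if (res$category == "complete") expect_true(all(det$prescribed))
    if (res$category == "none") expect_false(any(det$prescribed))
  }
})

test_that("stratified sampling is proportional, capped, seeded and exact", {
  mk <- function(id, ward) make_patient(patient_id = id, ward = ward)
  cohort <- c(lapply(sprintf("a%02d", 1:90), mk, ward = "big"),
              lapply(sprintf("b%02d", 1:10), mk, ward = "small"))
  s <- proportional_stratified_sample(cohort, 10, seed = 3)
  counts <- attr(s, "stratum_counts")
  expect_equal(counts[["big"]], 9L)
  expect_equal(counts[["small"]], 1L)
  expect_length(s, 10L)
  # reproducible
  ids <- function(x) vapply(x, `[[`, "", "patient_id")
  expect_identical(ids(proportional_stratified_sample(cohort, 10, seed = 3)),
                   ids(s))
  expect_false(identical(ids(proportional_stratified_sample(cohort, 10, seed = 4)),
                         ids(s)))
  expect_error(proportional_stratified_sample(cohort, 101, seed = 1), "exceeds")

  # 50 strata, n = 248: largest-remainder allocation sums exactly and
  # deviates < 1 from exact proportionality
  set.seed(99)
  sizes <- sample(5:60, 50, replace = TRUE)
  cohort <- unlist(lapply(seq_along(sizes), function(w)
    lapply(seq_len(sizes[w]), function(i)
      mk(sprintf("w%02d_%02d", w, i), sprintf("ward%02d", w)))),
    recursive = FALSE)
  s <- proportional_stratified_sample(cohort, 248, seed = 12)
  counts <- attr(s, "stratum_counts")
  expect_equal(sum(counts), 248L)
  exact <- 248 * sizes / sum(sizes)
  expect_true(all(abs(as.numeric(counts) - exact[order(sprintf("ward%02d", seq_along(sizes)))]) < 1))
  expect_length(s, 248L)
})

test_that("the Wald proportion interval matches closed-form arithmetic and clips at the edges", {
  ci <- proportion_ci(100, 248)
  expect_equal(round(ci$point, 1), 40.3)
  p <- 100 / 248; se <- sqrt(p * (1 - p) / 248); z <- qnorm(0.975)
  expect_equal(ci$lower, 100 * (p - z * se), tolerance = 1e-12)
  expect_equal(ci$upper, 100 * (p + z * se), tolerance = 1e-12)
  expect_equal(proportion_ci(0, 50), list(point = 0, lower = 0, upper = 0,
                                          k = 0, n = 50))
  expect_equal(proportion_ci(50, 50)$upper, 100)
  expect_error(proportion_ci(1, 0), "positive")
  expect_error(proportion_ci(5, 4), "k must be")
})

test_that("evaluate assembles the report with its documented arithmetic", {
  g <- generate_cohort(cohort_config(n_patients = 600, seed = 21))
  rep <- evaluate(g$cohort, g$sessions, sample_n = 200, seed = 5)
  expect_s3_class(rep, "empirx_eval_report")
  expect_equal(rep$n_eligible_extrapolated,
               extrapolate_eligible(rep$n_cohort, rep$k_eligible, 200))
  expect_equal(rep$usage_rate,
               usage_rate_pct(rep$n_sessions_total, rep$n_sessions_test,
                              rep$n_eligible_extrapolated))
  expect_equal(rep$n_used, rep$n_sessions_total - rep$n_sessions_test)
  expect_equal(rep$adherence$complete + rep$adherence$partial +
                 rep$adherence$none, rep$n_used)
  expect_equal(rep$adherence_rate,
               followed_rate_pct(rep$adherence$complete,
                                 rep$adherence$partial, rep$n_used))
  expect_equal(sum(rep$usage_by_diagnosis), rep$n_used)

  # zero sessions: usage 0, empty adherence
  rep0 <- evaluate(g$cohort, list(), sample_n = 200, seed = 5)
  expect_equal(rep0$usage_rate, 0)
  expect_equal(rep0$adherence, list(complete = 0L, partial = 0L, none = 0L))
  expect_error(evaluate(list(), list(), 10), "empty cohort")
})

test_that("the sample-based eligibility estimator covers the configured prevalence", {
  # nominal 95% Wald coverage at n = 248, p = 0.40; slight undercoverage of
  # the normal approximation is tolerated (>= 93%)
  reps <- 500
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    g <- generate_cohort(cohort_config(n_patients = 400,
                                       eligible_prevalence = 0.40,
                                       session_rate = 0, test_session_rate = 0,
                                       seed = 10000 + r))
    inc <- filter_cohort(g$cohort)
    samp <- proportional_stratified_sample(inc, 248, seed = r)
    k <- sum(vapply(samp, function(p) length(p$diagnoses) > 0, logical(1)))
    ci <- proportion_ci(k, 248)
    covered[r] <- ci$lower <= 40 && 40 <= ci$upper
  }
  expect_gte(mean(covered), 0.93)
})
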