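# The example knowledge base: seven diagnosis pathways (sepsis, pneumonia,
# urinary tract infection, fever of unknown origin, meningitis, secondary
# peritonitis, liver abscess) with an IgE-allergy question and an
# antibiogram-review gate in every pathway, plus renal dose tables for the
# advised drugs. The content is ILLUSTRATIVE: it mirrors the structure of a
# hospital guideline (HAP and high-risk CAP -> piperacillin-tazobactam,
# uncomplicated UTI -> nitrofurantoin, gentamicin dosed on ideal body
# weight) but is not a clinical product.

#' The seven diagnoses covered by the example knowledge base
#'
#' @return character vector of diagnosis names.
#' @export
cdss_diagnoses <- function() {
  c("sepsis", "pneumonia", "urinary_tract_infection", "fever_unknown_origin",
    "meningitis", "secondary_peritonitis", "liver_abscess")
}

reg <- function(..., duration = NA_real_, alternatives = list(), notes = "") {
  drugs <- list(...)
  list(drugs = lapply(drugs, function(d) list(drug = d[[1L]], route = d[[2L]])),
       duration_days = duration, alternatives = alternatives, notes = notes)
}

q <- function(prompt, edges, data_binding = NULL) {
  out <- list(kind = "question", prompt = prompt, edges = edges)
  if (!is.null(data_binding)) out$data_binding <- data_binding
  out
}
gate <- function(next_node, window_days = 183)
  list(kind = "gate", gate_kind = "antibiogram_review",
       window_days = window_days, `next` = next_node)
adv <- function(regimen) list(kind = "advice", regimen = regimen)
adv_consult <- function() list(kind = "advice", consult = TRUE)

# Standard renal bands: [50,Inf), [30,50), [10,30), [0,10); consult rows
# carry no dose. Half-open on eGFR.
bands4 <- function(d50, d30, d10, d0 = NULL, unit = "mg",
                   weight_basis = "none", pregnancy_allowed = TRUE) {
  row <- function(lo, hi, spec) {
    if (is.null(spec))
      list(egfr_min = lo, egfr_max = hi, consult = TRUE,
           pregnancy_allowed = pregnancy_allowed)
    else
      list(egfr_min = lo, egfr_max = hi, dose = spec[[1L]], unit = unit,
           interval_hours = spec[[2L]], weight_basis = weight_basis,
           pregnancy_allowed = pregnancy_allowed)
  }
  list(rows = list(row(50, Inf, d50), row(30, 50, d30),
                   row(10, 30, d10), row(0, 10, d0)),
       fallback = "consult")
}
flat_band <- function(dose, interval, unit = "mg", pregnancy_allowed = TRUE) {
  list(rows = list(list(egfr_min = 0, egfr_max = Inf, dose = dose, unit = unit,
                        interval_hours = interval,
                        pregnancy_allowed = pregnancy_allowed)),
       fallback = "consult")
}

example_kb_list <- function() {
  allergy_q <- function(yes, no)
    q("Does the patient have an IgE-mediated beta-lactam allergy?",
      list(yes = yes, no = no), data_binding = "allergy_penicillin_ige")

  piptazo <- reg(list("piperacillin-tazobactam", "iv"), duration = c(5, 7),
                 alternatives = list(reg(list("ciprofloxacin", "iv"),
                                         duration = c(5, 7))))
  ceftr_gent <- reg(list("ceftriaxone", "iv"), list("gentamicin", "iv"),
                    duration = 7,
                    alternatives = list(
                      reg(list("ciprofloxacin", "iv"), list("gentamicin", "iv"),
                          duration = 7)))
  cipro_gent <- reg(list("ciprofloxacin", "iv"), list("gentamicin", "iv"),
                    duration = 7)
  ceftr_metro <- reg(list("ceftriaxone", "iv"), list("metronidazole", "iv"),
                     duration = 7,
                     alternatives = list(
                       reg(list("ciprofloxacin", "iv"),
                           list("metronidazole", "iv"), duration = 7)))

  list(
    version = "1.0",
    diagnoses = list(
      pneumonia = list(
        root = "q_onset",
        nodes = list(
          q_onset = q("Hospital-acquired (onset > 48 h after admission) or community-acquired pneumonia?",
                      list(hap = "q_allergy_hap", cap = "q_curb")),
          q_allergy_hap = allergy_q(yes = "gate_pen", no = "gate_severe"),
          q_curb = q("CURB-65 risk level",
                     list(low = "gate_cap_low", moderate = "gate_cap_mod",
                          high = "q_allergy_high")),
          q_allergy_high = allergy_q(yes = "gate_pen", no = "gate_severe"),
          gate_cap_low = gate("adv_cap_low"),
          gate_cap_mod = gate("adv_cap_mod"),
          gate_severe = gate("adv_severe"),
          gate_pen = gate("adv_pen_allergy"),
          adv_cap_low = adv(reg(list("amoxicillin", "oral"), duration = 5,
                                alternatives = list(reg(list("doxycycline", "oral"),
                                                        duration = 5)))),
          adv_cap_mod = adv(reg(list("ceftriaxone", "iv"), duration = 5,
                                alternatives = list(reg(list("ciprofloxacin", "iv"),
                                                        duration = 5)))),
          adv_severe = adv(piptazo),
          adv_pen_allergy = adv(reg(list("ciprofloxacin", "iv"),
                                    duration = c(5, 7)))
        )
      ),
      urinary_tract_infection = list(
        root = "q_complicated",
        nodes = list(
          q_complicated = q("Cystitis without systemic symptoms (uncomplicated) or complicated urinary tract infection?",
                            list(uncomplicated = "q_pregnant", complicated = "q_allergy_uti")),
          q_pregnant = q("Is the patient pregnant?",
                         list(yes = "gate_uti_preg", no = "gate_uti_unc"),
                         data_binding = "pregnant"),
          q_allergy_uti = allergy_q(yes = "gate_uti_pen", no = "gate_uti_comp"),
          gate_uti_unc = gate("adv_uti_unc"),
          gate_uti_preg = gate("adv_uti_preg"),
          gate_uti_comp = gate("adv_uti_comp"),
          gate_uti_pen = gate("adv_uti_pen"),
          adv_uti_unc = adv(reg(list("nitrofurantoin", "oral"), duration = 5,
                                alternatives = list(reg(list("ciprofloxacin", "oral"),
                                                        duration = 3)))),
          adv_uti_preg = adv(reg(list("amoxicillin", "oral"), duration = 5)),
          adv_uti_comp = adv(reg(list("ciprofloxacin", "iv"), duration = 10,
                                 alternatives = list(reg(list("gentamicin", "iv"),
                                                         duration = 7)))),
          adv_uti_pen = adv(reg(list("ciprofloxacin", "iv"), duration = 10))
        )
      ),
      sepsis = list(
        root = "q_allergy_sep",
        nodes = list(
          q_allergy_sep = allergy_q(yes = "gate_sep_pen", no = "gate_sep"),
          gate_sep = gate("adv_sep"),
          gate_sep_pen = gate("adv_sep_pen"),
          adv_sep = adv(ceftr_gent),
          adv_sep_pen = adv(cipro_gent)
        )
      ),
      fever_unknown_origin = list(
        root = "q_neutro",
        nodes = list(
          q_neutro = q("Is the patient neutropenic (absolute neutrophils < 0.5 x 1e9/L)?",
                       list(yes = "adv_fuo_consult", no = "q_allergy_fuo"),
                       data_binding = "neutropenic"),
          q_allergy_fuo = allergy_q(yes = "gate_fuo_pen", no = "gate_fuo"),
          gate_fuo = gate("adv_fuo"),
          gate_fuo_pen = gate("adv_fuo_pen"),
          adv_fuo = adv(reg(list("ceftriaxone", "iv"), duration = 7,
                            alternatives = list(reg(list("ciprofloxacin", "iv"),
                                                    duration = 7)))),
          adv_fuo_pen = adv(reg(list("ciprofloxacin", "iv"), duration = 7)),
          adv_fuo_consult = adv_consult()
        )
      ),
      meningitis = list(
        root = "q_allergy_men",
        nodes = list(
          q_allergy_men = allergy_q(yes = "gate_men_pen", no = "gate_men"),
          gate_men = gate("adv_men"),
          gate_men_pen = gate("adv_men_consult"),
          adv_men = adv(reg(list("ceftriaxone", "iv"), duration = 10)),
          adv_men_consult = adv_consult()
        )
      ),
      secondary_peritonitis = list(
        root = "q_allergy_per",
        nodes = list(
          q_allergy_per = allergy_q(yes = "gate_per_pen", no = "gate_per"),
          gate_per = gate("adv_per"),
          gate_per_pen = gate("adv_per_consult"),
          adv_per = adv(ceftr_metro),
          adv_per_consult = adv_consult()
        )
      ),
      liver_abscess = list(
        root = "q_allergy_liv",
        nodes = list(
          q_allergy_liv = allergy_q(yes = "gate_liv_pen", no = "gate_liv"),
          gate_liv = gate("adv_liv"),
          gate_liv_pen = gate("adv_liv_consult"),
          adv_liv = adv(ceftr_metro),
          adv_liv_consult = adv_consult()
        )
      )
    ),
    dose_rules = list(
      "piperacillin-tazobactam" = bands4(list(4000, 6), list(4000, 8),
                                         list(4000, 12), NULL),
      "amoxicillin" = bands4(list(500, 8), list(500, 8), list(500, 12), NULL),
      "ceftriaxone" = flat_band(2000, 24),
      "ciprofloxacin" = bands4(list(400, 12), list(400, 12), list(400, 24),
                               NULL, pregnancy_allowed = FALSE),
      "gentamicin" = list(
        rows = list(
          list(egfr_min = 50, egfr_max = Inf, dose = 5, unit = "mg/kg",
               interval_hours = 24, weight_basis = "ideal",
               pregnancy_allowed = FALSE),
          list(egfr_min = 30, egfr_max = 50, dose = 5, unit = "mg/kg",
               interval_hours = 36, weight_basis = "ideal",
               pregnancy_allowed = FALSE),
          list(egfr_min = 10, egfr_max = 30, consult = TRUE,
               pregnancy_allowed = FALSE),
          list(egfr_min = 0, egfr_max = 10, consult = TRUE,
               pregnancy_allowed = FALSE)),
        fallback = "consult"),
      "nitrofurantoin" = list(
        rows = list(
          list(egfr_min = 50, egfr_max = Inf, dose = 50, unit = "mg",
               interval_hours = 6, pregnancy_allowed = TRUE),
          list(egfr_min = 30, egfr_max = 50, consult = TRUE,
               pregnancy_allowed = TRUE),
          list(egfr_min = 10, egfr_max = 30, consult = TRUE,
               pregnancy_allowed = TRUE),
          list(egfr_min = 0, egfr_max = 10, consult = TRUE,
               pregnancy_allowed = TRUE)),
        fallback = "consult"),
      "metronidazole" = flat_band(500, 8),
      "doxycycline" = flat_band(100, 12, pregnancy_allowed = FALSE)
    )
  )
}

#' Load the example knowledge base
#'
#' Builds the illustrative seven-diagnosis knowledge base in memory. The
#' same content ships as `inst/extdata/example-kb.yaml`.
#'
#' @return an `empirx_kb`.
#' @export
load_example_kb <- function() {
  kb_from_list(example_kb_list(), source = "<example-kb>")
}

#' Write the example knowledge base to a YAML file
#'
#' @param path output path; defaults to `example-kb.yaml` in the working
#'   directory.
#' @return the loaded `empirx_kb`, invisibly.
#' @export
generate_example_kb <- function(path = "example-kb.yaml") {
  x <- example_kb_list()
  yaml::write_yaml(x, path, indent.mapping.sequence = TRUE,
                   handlers = list(logical = yaml::verbatim_logical))
  invisible(load_kb(path))
}
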