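#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a timestamp to UTC POSIXct
#'
#' Accepts POSIXct, `YYYY-MM-DDTHH:MM:SSZ`, or `YYYY-MM-DD[ HH:MM:SS]`.
#' All timestamps in the package are UTC.
#' @noRd
parse_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.null(x) || length(x) == 0L) return(as.POSIXct(character(), tz = "UTC"))
  x <- as.character(x)
  x <- sub("Z$", "", sub("T", " ", x, fixed = TRUE))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

format_time <- function(x) {
  ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

parse_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(as.character(x))
}

#' Truncate a percentage to one decimal
#'
#' Report rates are printed truncated, not rounded, to one decimal place
#' (114/169 -> 67.4).
#' @noRd
trunc1 <- function(x) trunc(x * 10) / 10

#' Normalize a dose to milligrams; NA when the unit is not mass-convertible
#' (per-kg doses are compared on amount + unit instead).
#' @noRd
to_mg <- function(amount, unit) {
  if (is.na(amount) || is.na(unit)) return(NA_real_)
  switch(unit, mg = amount, g = amount * 1000, NA_real_)
}

# Run code with a temporarily seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

.drug_classes <- c(
  "amoxicillin"             = "penicillin",
  "piperacillin-tazobactam" = "penicillin",
  "pheneticillin"           = "penicillin",
  "amoxicillin-clavulanate" = "penicillin",
  "ceftriaxone"             = "cephalosporin",
  "cefazolin"               = "cephalosporin",
  "cefuroxime"              = "cephalosporin",
  "ciprofloxacin"           = "fluoroquinolone",
  "gentamicin"              = "aminoglycoside",
  "nitrofurantoin"          = "nitrofuran",
  "metronidazole"           = "nitroimidazole",
  "doxycycline"             = "tetracycline",
  "cotrimoxazole"           = "sulfonamide",
  "clindamycin"             = "lincosamide"
)

.drug_atc <- c(
  "amoxicillin"             = "J01CA04",
  "piperacillin-tazobactam" = "J01CR05",
  "pheneticillin"           = "J01CE05",
  "amoxicillin-clavulanate" = "J01CR02",
  "ceftriaxone"             = "J01DD04",
  "cefazolin"               = "J01DB04",
  "cefuroxime"              = "J01DC02",
  "ciprofloxacin"           = "J01MA02",
  "gentamicin"              = "J01GB03",
  "nitrofurantoin"          = "J01XE01",
  "metronidazole"           = "J01XD01",
  "doxycycline"             = "J01AA02",
  "cotrimoxazole"           = "J01EE01",
  "clindamycin"             = "J01FF01"
)

#' Pharmacological class of a drug identifier
#'
#' Small illustrative mapping covering the drugs used by the example
#' knowledge base and the prophylaxis rules. Unknown drugs map to `"other"`.
#'
#' @param drug character vector of drug identifiers.
#' @return character vector of class labels.
#' @export
#' @examples
#' drug_class_of(c("amoxicillin", "gentamicin"))
drug_class_of <- function(drug) {
  out <- unname(.drug_classes[drug])
  out[is.na(out)] <- "other"
  out
}

atc_of <- function(drug) {
  out <- unname(.drug_atc[drug])
  out[is.na(out)] <- "J01XX00"
  out
}

# Does a recorded allergy entry hit this drug? Matches on the drug id, its
# class, or the umbrella class "beta_lactam" (penicillins + cephalosporins).
allergy_hits_drug <- function(allergy_class, drug) {
  dc <- drug_class_of(drug)
  allergy_class == drug | allergy_class == dc |
    (allergy_class == "beta_lactam" & dc %in% c("penicillin", "cephalosporin"))
}
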