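# Clinical calculators surfaced by the advisor: CURB-65 severity for
# community-acquired pneumonia, Devine ideal body weight (used for
# gentamicin dosing), and BMI.

#' CURB-65 pneumonia severity score
#'
#' One point each for Confusion, Urea > 7 mmol/L, Respiratory rate >= 30
#' /min, low Blood pressure (systolic < 90 mmHg or diastolic <= 60 mmHg),
#' and age >= 65 years. Risk mapping: 0-1 low, 2 moderate, >= 3 high.
#'
#' @param confusion logical, new-onset confusion.
#' @param urea serum urea in mmol/L.
#' @param respiratory_rate breaths per minute.
#' @param systolic_bp,diastolic_bp blood pressure in mmHg.
#' @param age age in years.
#' @return list with integer `score` (0-5) and `risk`
#'   (`"low"`/`"moderate"`/`"high"`).
#' @export
#' @examples
#' curb65(FALSE, 5, 18, 120, 80, 40)  # score 0, low
#' curb65(TRUE, 9, 32, 85, 55, 70)    # score 5, high
curb65 <- function(confusion, urea, respiratory_rate,
                   systolic_bp, diastolic_bp, age) {
  vals <- c(urea = urea, respiratory_rate = respiratory_rate,
            systolic_bp = systolic_bp, diastolic_bp = diastolic_bp, age = age)
  if (any(is.na(vals)) || is.na(confusion))
    stop("curb65: all inputs must be present")
  if (any(vals < 0))
    stop("curb65: negative input: ", paste(names(vals)[vals < 0], collapse = ", "))
  score <- sum(isTRUE(confusion),
               urea > 7,
               respiratory_rate >= 30,
               systolic_bp < 90 || diastolic_bp <= 60,
               age >= 65)
  risk <- if (score <= 1) "low" else if (score == 2) "moderate" else "high"
  list(score = as.integer(score), risk = risk)
}

#' Devine ideal body weight
#'
#' Male: 50 kg + 0.9055 kg per cm above 152.4 cm; female: 45.5 kg +
#' 0.9055 kg per cm above 152.4 cm. For heights below 152.4 cm the base
#' value is returned (the formula is floored rather than extrapolated
#' downwards).
#'
#' @param sex `"male"` or `"female"`.
#' @param height_cm body height in cm, > 0.
#' @return ideal body weight in kg.
#' @export
#' @examples
#' ideal_body_weight("male", 180)   # ~74.99
ideal_body_weight <- function(sex, height_cm) {
  sex <- match.arg(sex, c("male", "female"))
  if (is.na(height_cm) || height_cm <= 0)
    stop("ideal_body_weight: height must be positive")
  base <- if (sex == "male") 50 else 45.5
  base + 0.9055 * max(0, height_cm - 152.4)
}

#' Body mass index
#'
#' @param weight_kg body weight in kg, > 0.
#' @param height_cm body height in cm, > 0.
#' @return BMI in kg/m2.
#' @export
#' @examples
#' bmi(80, 200)  # 20
bmi <- function(weight_kg, height_cm) {
  if (is.na(weight_kg) || is.na(height_cm) || weight_kg <= 0 || height_cm <= 0)
    stop("bmi: weight and height must be positive")
  weight_kg / (height_cm / 100)^2
}
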