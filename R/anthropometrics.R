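#' Body mass index
#'
#' @param weight_kg Body weight in kilograms, strictly positive.
#' @param height_cm Height in centimetres, strictly positive.
#'
#' @return BMI in kg/m^2. Vectorised over both arguments.
#' @examples
#' compute_bmi(70, 170)
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  assert_positive(weight_kg, "weight_kg")
  assert_positive(height_cm, "height_cm")
  weight_kg / (height_cm / 100)^2
}

#' Ideal body weight by the Devine formula
#'
#' Male: 50 kg + 2.3 kg per inch of height over 60 in; female: 45.5 kg +
#' 2.3 kg per inch over 60 in (1 in = 2.54 cm). The line is extrapolated
#' below 60 in (152.4 cm), where the formula was never validated: heights in
#' \[130, 152.4) cm trigger a warning and heights below 130 cm are rejected.
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @param height_cm Height in centimetres; must be at least 130.
#' @param warn Emit the short-stature extrapolation warning? Set to `FALSE`
#'   when a caller has already validated the height range.
#'
#' @return Ideal body weight in kilograms.
#' @examples
#' compute_ibw_devine("male", 177.8)
#' @export
compute_ibw_devine <- function(sex, height_cm, warn = TRUE) {
  assert_positive(height_cm, "height_cm")
  sex <- match_sex(sex)
  if (any(height_cm < 130)) {
    stop("height below 130 cm is outside the validated range of the Devine formula",
         call. = FALSE)
  }
  if (warn && any(height_cm < 152.4)) {
    warning("height below 152.4 cm (60 in): Devine formula extrapolated downward",
            call. = FALSE)
  }
  inches <- height_cm / 2.54
  base <- ifelse(sex == "male", 50, 45.5)
  base + 2.3 * (inches - 60)
}

#' Calculation weight for local anesthetic dosing
#'
#' Applies the five-branch rule selecting the weight that multiplies the
#' per-kg dose limit, then caps it at 70 kg:
#'
#' 1. AW <= 70, BMI < 30, IBW > AW: CW = AW
#' 2. AW <= 70, BMI < 30, IBW <= AW: CW = IBW
#' 3. AW <= 70, BMI >= 30: CW = IBW
#' 4. AW > 70 and IBW > 70: CW = 70
#' 5. AW > 70 and IBW <= 70: CW = IBW
#'
#' The branches are exhaustive and mutually exclusive for any positive
#' (AW, IBW, BMI); exactly one fires and its index is recorded.
#'
#' @param aw Actual weight, kg.
#' @param ibw Ideal body weight, kg (see [compute_ibw_devine()]).
#' @param bmi Body mass index, kg/m^2 (see [compute_bmi()]).
#'
#' @return A tibble with columns `ibw`, `bmi`, `cw` (capped at 70) and
#'   `cw_rule` (integer 1-5). Vectorised; one row per input.
#' @examples
#' determine_calculation_weight(aw = 100, ibw = 80, bmi = 29)
#' @export
determine_calculation_weight <- function(aw, ibw, bmi) {
  assert_positive(aw, "aw")
  assert_positive(ibw, "ibw")
  assert_positive(bmi, "bmi")
  rule <- dplyr::case_when(
    aw <= 70 & bmi < 30 & ibw > aw  ~ 1L,
    aw <= 70 & bmi < 30 & ibw <= aw ~ 2L,
    aw <= 70 & bmi >= 30            ~ 3L,
    aw > 70 & ibw > 70              ~ 4L,
    aw > 70 & ibw <= 70             ~ 5L
  )
  cw_raw <- dplyr::case_when(
    rule == 1L ~ aw,
    rule == 2L ~ ibw,
    rule == 3L ~ ibw,
    rule == 4L ~ 70,
    rule == 5L ~ ibw
  )
  tibble::tibble(ibw = ibw, bmi = bmi, cw = pmin(cw_raw, 70), cw_rule = rule)
}

#' Anthropometric work-up of a patient
#'
#' Computes BMI, Devine ideal body weight and the capped calculation weight
#' for one patient record in a single call.
#'
#' @param patient A [patient_record()].
#' @param warn Passed to [compute_ibw_devine()].
#' @return One-row tibble: `ibw`, `bmi`, `cw`, `cw_rule`.
#' @export
anthropometrics <- function(patient, warn = TRUE) {
  stopifnot(inherits(patient, "patient_record"))
  bmi <- compute_bmi(patient$weight_kg, patient$height_cm)
  ibw <- compute_ibw_devine(patient$sex, patient$height_cm, warn = warn)
  determine_calculation_weight(patient$weight_kg, ibw, bmi)
}
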