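#' Patient record
#'
#' Validated container for the demographic, anthropometric and risk-factor
#' state of one (possibly simulated) patient. Organ-function markers left
#' `NA` mean "not reported" and are treated as the absence of the
#' corresponding risk factor, never as a value of zero.
#'
#' @param age Age in whole years, >= 0.
#' @param sex `"male"` or `"female"`.
#' @param height_cm Height in centimetres, > 0.
#' @param weight_kg Actual body weight (AW) in kilograms, > 0.
#' @param gfr Glomerular filtration rate, mL/min, or `NA` if not reported.
#' @param prothrombin_pct Prothrombin time as percent of normal, or `NA`.
#' @param lvef_pct Left ventricular ejection fraction, percent, or `NA`.
#' @param pregnant Logical; currently pregnant?
#' @param medications Character vector of drug names (free text, matched
#'   case-insensitively against the inhibitor list).
#'
#' @return An object of class `patient_record`.
#' @examples
#' patient_record(age = 72, sex = "female", height_cm = 160, weight_kg = 58,
#'                gfr = 40)
#' @export
patient_record <- function(age, sex, height_cm, weight_kg,
                           gfr = NA_real_, prothrombin_pct = NA_real_,
                           lvef_pct = NA_real_, pregnant = FALSE,
                           medications = character()) {
  assert_scalar_number(age, "age")
  if (age < 0) stop("`age` must be >= 0", call. = FALSE)
  sex <- match_sex(sex)
  assert_scalar_number(height_cm, "height_cm")
  assert_positive(height_cm, "height_cm")
  assert_scalar_number(weight_kg, "weight_kg")
  assert_positive(weight_kg, "weight_kg")
  for (nm in c("gfr", "prothrombin_pct", "lvef_pct")) {
    v <- get(nm)
    if (!(length(v) == 1 && (is.na(v) || (is.numeric(v) && is.finite(v) && v >= 0)))) {
      stop("`", nm, "` must be a single nonnegative number or NA", call. = FALSE)
    }
  }
  stopifnot(is.logical(pregnant), length(pregnant) == 1, !is.na(pregnant))
  stopifnot(is.character(medications))
  structure(
    list(age = as.integer(age), sex = sex, height_cm = as.numeric(height_cm),
         weight_kg = as.numeric(weight_kg), gfr = as.numeric(gfr),
         prothrombin_pct = as.numeric(prothrombin_pct),
         lvef_pct = as.numeric(lvef_pct), pregnant = pregnant,
         medications = medications),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s, %d y, %.0f cm, %.1f kg\n",
              x$sex, x$age, x$height_cm, x$weight_kg))
  markers <- c(GFR = x$gfr, PT = x$prothrombin_pct, LVEF = x$lvef_pct)
  markers <- markers[!is.na(markers)]
  if (length(markers)) {
    cat("  markers:", paste(names(markers), markers, sep = "=", collapse = ", "), "\n")
  }
  if (x$pregnant) cat("  pregnant\n")
  if (length(x$medications)) cat("  medications:", paste(x$medications, collapse = ", "), "\n")
  invisible(x)
}
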