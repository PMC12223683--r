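#' Metabolic risk-factor assessment
#'
#' Flags the six factors that slow local anesthetic clearance and maps their
#' count to the multiplicative dose adjustment: age >= 70 years; renal
#' dysfunction (GFR < 50 mL/min); hepatic dysfunction (prothrombin time
#' < 50%); heart failure (LVEF <= 30%); pregnancy; and use of a major
#' CYP1A2/CYP3A inhibitor. One factor reduces the maximum dose by 20%
#' (factor 0.8); two or more reduce it by 30% (factor 0.7). Markers left
#' `NA` on the record contribute no factor.
#'
#' @param patient A [patient_record()].
#' @param inhibitors Character vector of inhibitor drug names; defaults to
#'   the bundled list. Matching is case-insensitive and exact.
#'
#' @return An object of class `risk_assessment`: list with
#'   `factors_present` (character), `n_factors` and `adjustment_factor`
#'   (1.0, 0.8 or 0.7).
#' @examples
#' p <- patient_record(age = 72, sex = "male", height_cm = 175, weight_kg = 80,
#'                     gfr = 40)
#' assess_risk_factors(p)
#' @export
assess_risk_factors <- function(patient, inhibitors = default_inhibitor_list()) {
  stopifnot(inherits(patient, "patient_record"))
  flags <- c(
    "age>=70"       = patient$age >= 70,
    "renal"         = !is.na(patient$gfr) && patient$gfr < 50,
    "hepatic"       = !is.na(patient$prothrombin_pct) && patient$prothrombin_pct < 50,
    "heart_failure" = !is.na(patient$lvef_pct) && patient$lvef_pct <= 30,
    "pregnancy"     = isTRUE(patient$pregnant),
    "cyp_inhibitor" = any(tolower(patient$medications) %in% tolower(inhibitors))
  )
  n <- sum(flags)
  structure(
    list(factors_present = names(flags)[flags],
         n_factors = n,
         adjustment_factor = if (n == 0) 1.0 else if (n == 1) 0.8 else 0.7),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> %d factor(s)%s; dose adjustment x%.1f\n",
              x$n_factors,
              if (x$n_factors) paste0(" [", paste(x$factors_present, collapse = ", "), "]") else "",
              x$adjustment_factor))
  invisible(x)
}
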