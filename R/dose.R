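#' Convert a maximum dose in mg to a maximum volume in mL
#'
#' The clinically administered quantity is a volume, so the mg maximum is
#' converted through the solution concentration and rounded *down* to the
#' nearest whole millilitre: the reported volume never delivers more drug
#' than the mg maximum.
#'
#' @param max_mg Maximum dose in milligrams, >= 0.
#' @param concentration Solution concentration in mg/mL, > 0.
#' @return Nonnegative integer number of millilitres.
#' @examples
#' mg_to_max_volume(209, 7.5)
#' @export
mg_to_max_volume <- function(max_mg, concentration) {
  if (!is.numeric(max_mg) || any(!is.finite(max_mg)) || any(max_mg < 0)) {
    stop("`max_mg` must be nonnegative and finite", call. = FALSE)
  }
  assert_positive(concentration, "concentration")
  # round() guards against 1-ulp descents of exact quotients before flooring
  as.integer(floor(round(max_mg / concentration, 9)))
}

#' Maximum safe dose of one local anesthetic
#'
#' Computes the reference maximum under one of three modes:
#' \describe{
#'   \item{`comprehensive`}{calculation weight (see
#'     [determine_calculation_weight()]) times the per-kg dose limit, times
#'     the risk-factor adjustment (see [assess_risk_factors()]). This is the
#'     most conservative rule chain and the default.}
#'   \item{`simplified_aw`}{actual weight times the dose limit.}
#'   \item{`simplified_ibw`}{Devine ideal body weight times the dose limit.}
#' }
#' When the drug carries a concentration the equivalent maximum volume is
#' attached, floored to whole millilitres. mg values are never rounded.
#'
#' @param patient A [patient_record()].
#' @param drug An [anesthetic_spec()]; `dose_limit` is mandatory.
#' @param mode One of `"comprehensive"`, `"simplified_aw"`, `"simplified_ibw"`.
#' @param inhibitors Inhibitor list for the risk assessment.
#' @param warn Passed to [compute_ibw_devine()].
#'
#' @return An object of class `dose_result`: `max_mg`, `max_ml` (integer or
#'   `NA`), `mode`, `drug`, `concentration` and `trace`, the ordered list of
#'   rules applied.
#' @examples
#' p <- patient_record(age = 45, sex = "male", height_cm = 178, weight_kg = 70)
#' max_safe_dose(p, anesthetic_spec("ropivacaine", 3, 7.5))
#' @export
max_safe_dose <- function(patient, drug,
                          mode = c("comprehensive", "simplified_aw", "simplified_ibw"),
                          inhibitors = default_inhibitor_list(), warn = TRUE) {
  stopifnot(inherits(patient, "patient_record"))
  if (!inherits(drug, "anesthetic_spec")) {
    stop("`drug` must be an anesthetic_spec", call. = FALSE)
  }
  if (is.null(drug$dose_limit) || is.na(drug$dose_limit)) {
    stop("anesthetic `", drug$name, "` has no dose_limit configured", call. = FALSE)
  }
  mode <- match.arg(mode)
  trace <- character()

  if (mode == "comprehensive") {
    anth <- anthropometrics(patient, warn = warn)
    trace <- c(trace,
               sprintf("BMI = %.2f kg/m2; IBW (Devine) = %.2f kg", anth$bmi, anth$ibw),
               sprintf("CW rule %d: CW = %.2f kg (cap 70 kg)", anth$cw_rule, anth$cw))
    risk <- assess_risk_factors(patient, inhibitors)
    trace <- c(trace,
               sprintf("risk factors: %d%s -> adjustment x%.1f", risk$n_factors,
                       if (risk$n_factors) paste0(" (", paste(risk$factors_present, collapse = ", "), ")") else "",
                       risk$adjustment_factor))
    max_mg <- anth$cw * drug$dose_limit * risk$adjustment_factor
    trace <- c(trace, sprintf("max = %.2f kg x %.3g mg/kg x %.1f = %.2f mg",
                              anth$cw, drug$dose_limit, risk$adjustment_factor, max_mg))
  } else if (mode == "simplified_aw") {
    max_mg <- patient$weight_kg * drug$dose_limit
    trace <- c(trace, sprintf("simplified: AW %.2f kg x %.3g mg/kg = %.2f mg",
                              patient$weight_kg, drug$dose_limit, max_mg))
  } else {
    ibw <- compute_ibw_devine(patient$sex, patient$height_cm, warn = warn)
    max_mg <- ibw * drug$dose_limit
    trace <- c(trace, sprintf("simplified: IBW %.2f kg x %.3g mg/kg = %.2f mg",
                              ibw, drug$dose_limit, max_mg))
  }

  max_ml <- NA_integer_
  if (!is.na(drug$concentration)) {
    max_ml <- mg_to_max_volume(max_mg, drug$concentration)
    trace <- c(trace, sprintf("volume: floor(%.2f mg / %.3g mg/mL) = %d mL",
                              max_mg, drug$concentration, max_ml))
  }

  structure(
    list(max_mg = max_mg, max_ml = max_ml, mode = mode, drug = drug$name,
         concentration = drug$concentration, trace = trace),
    class = "dose_result"
  )
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> %s (%s): %.2f mg%s\n", x$drug, x$mode, x$max_mg,
              if (is.na(x$max_ml)) "" else sprintf(" = %d mL at %.3g mg/mL",
                                                   x$max_ml, x$concentration)))
  for (line in x$trace) cat("  -", line, "\n")
  cat("  research use only - not for clinical decision-making\n")
  invisible(x)
}

#' Maximum safe doses for a mixture of local anesthetics
#'
#' Under fractional additive toxicity the components share one toxicity
#' budget: component i may use `proportion_i` of its own stand-alone
#' maximum, so that the budget fractions `dose_i / max_i` sum to one.
#'
#' @param patient A [patient_record()].
#' @param plan A [mixture_plan()].
#' @inheritParams max_safe_dose
#' @return List of `dose_result`, one per component, in plan order.
#' @examples
#' cat <- default_drug_catalogue()
#' p <- patient_record(age = 45, sex = "male", height_cm = 178, weight_kg = 70)
#' max_safe_mixture(p, mixture_plan(list(cat$lidocaine, cat$ropivacaine), c(0.5, 0.5)))
#' @export
max_safe_mixture <- function(patient, plan,
                             mode = c("comprehensive", "simplified_aw", "simplified_ibw"),
                             inhibitors = default_inhibitor_list(), warn = TRUE) {
  stopifnot(inherits(plan, "mixture_plan"))
  mode <- match.arg(mode)
  out <- vector("list", length(plan$drugs))
  for (i in seq_along(plan$drugs)) {
    standalone <- max_safe_dose(patient, plan$drugs[[i]], mode = mode,
                                inhibitors = inhibitors, warn = warn)
    res <- standalone
    res$max_mg <- plan$proportions[i] * standalone$max_mg
    res$trace <- c(standalone$trace,
                   sprintf("mixture share %.3g of stand-alone %.2f mg = %.2f mg",
                           plan$proportions[i], standalone$max_mg, res$max_mg))
    if (!is.na(res$concentration)) {
      res$max_ml <- mg_to_max_volume(res$max_mg, res$concentration)
      res$trace <- c(res$trace, sprintf("volume: floor(%.2f / %.3g) = %d mL",
                                        res$max_mg, res$concentration, res$max_ml))
    }
    out[[i]] <- res
  }
  names(out) <- vapply(plan$drugs, `[[`, character(1), "name")
  out
}

#' Is a candidate dose an overdose?
#'
#' An overdose is a candidate dose *strictly* exceeding the reference
#' maximum in its own unit; a candidate exactly equal to the maximum is
#' safe. A mL candidate is compared against the floored maximum volume;
#' when the reference has no volume, the candidate is converted to mg
#' through the concentration (error if none is available).
#'
#' @param candidate Candidate dose, numeric.
#' @param reference A `dose_result`.
#' @param unit `"mg"` or `"mL"`, the candidate's unit.
#' @return Logical.
#' @examples
#' p <- patient_record(age = 45, sex = "male", height_cm = 178, weight_kg = 70)
#' ref <- max_safe_dose(p, anesthetic_spec("ropivacaine", 3, 7.5))
#' is_overdose(ref$max_mg, ref, "mg")
#' @export
is_overdose <- function(candidate, reference, unit = c("mg", "mL")) {
  stopifnot(inherits(reference, "dose_result"))
  assert_scalar_number(candidate, "candidate")
  unit <- match.arg(unit)
  if (unit == "mg") return(candidate > reference$max_mg)
  if (!is.na(reference$max_ml)) return(candidate > reference$max_ml)
  if (!is.na(reference$concentration)) {
    return(candidate * reference$concentration > reference$max_mg)
  }
  stop("candidate is in mL but the reference has neither a maximum volume ",
       "nor a concentration to convert with", call. = FALSE)
}
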