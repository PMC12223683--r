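#' Normalize a candidate response to a single value
#'
#' A single value stands for itself; for a suggested range the *lowest*
#' dose advised is used; an abstention becomes `NA` and is excluded from
#' rate denominators downstream.
#'
#' @param kind `"value"`, `"range"` or `"abstain"`.
#' @param value Dose for `kind = "value"`.
#' @param low,high Range endpoints for `kind = "range"` (`low <= high`).
#' @return A positive number, or `NA_real_` for an abstention.
#' @examples
#' normalize_response("range", low = 15, high = 22)
#' @export
normalize_response <- function(kind, value = NA_real_, low = NA_real_, high = NA_real_) {
  kind <- match.arg(kind, c("value", "range", "abstain"))
  if (kind == "abstain") return(NA_real_)
  out <- if (kind == "value") {
    assert_scalar_number(value, "value")
    value
  } else {
    assert_scalar_number(low, "low")
    assert_scalar_number(high, "high")
    if (low > high) stop("range must have low <= high", call. = FALSE)
    low
  }
  if (out <= 0) stop("a dose must be strictly positive", call. = FALSE)
  out
}

#' Grade one candidate dose against one reference dose
#'
#' Status is `"missing"` for an abstention, `"unsafe"` when the candidate
#' strictly exceeds the reference, `"safe"` otherwise. For unsafe cases the
#' percent exceedance `(candidate - reference) / reference * 100` and the
#' absolute exceedance `candidate - reference` (in the vignette's own unit)
#' are attached; they are absent (`NA`), not zero, for safe cases.
#'
#' @param candidate Normalized candidate dose, or `NA` for an abstention.
#' @param reference Reference maximum in the same unit, > 0.
#' @param unit `"mg"` or `"mL"` (annotation only; both sides must already
#'   share it).
#' @param mixture Logical flag carried through to the output.
#' @return One-row tibble: `status`, `candidate_value`, `reference_value`,
#'   `unit`, `mixture`, `exceedance_pct`, `exceedance_abs`.
#' @examples
#' evaluate_case(240, 110, "mg")
#' @export
evaluate_case <- function(candidate, reference, unit = c("mg", "mL"), mixture = FALSE) {
  unit <- match.arg(unit)
  assert_scalar_number(reference, "reference")
  assert_positive(reference, "reference")
  if (!is.na(candidate)) assert_scalar_number(candidate, "candidate")
  status <- if (is.na(candidate)) "missing"
            else if (candidate > reference) "unsafe"
            else "safe"
  unsafe <- status == "unsafe"
  tibble::tibble(
    status = status,
    candidate_value = as.numeric(candidate),
    reference_value = reference,
    unit = unit,
    mixture = isTRUE(mixture),
    exceedance_pct = if (unsafe) (candidate - reference) / reference * 100 else NA_real_,
    exceedance_abs = if (unsafe) candidate - reference else NA_real_
  )
}

#' Grade a panel of responses against reference doses
#'
#' Joins candidate responses to per-vignette references, normalizes each
#' response (range -> low endpoint, abstention -> missing) and classifies
#' it. When a response's declared unit differs from the reference unit the
#' candidate is converted through the drug's concentration; without one the
#' case is an error.
#'
#' @param responses Tibble with columns `vignette_id`, `respondent_id`,
#'   `kind`, `value`, `low`, `high`, `unit`.
#' @param references Tibble with columns `vignette_id`, `drug`, `unit`,
#'   `reference` and logical `mixture`.
#' @param concentrations Optional named numeric vector (mg/mL by drug name)
#'   used only to reconcile mismatched units.
#' @return Tibble of case evaluations, one row per response, with the
#'   columns of [evaluate_case()] plus ids, `drug` and `unit_converted`.
#' @export
evaluate_responses <- function(responses, references, concentrations = NULL) {
  req <- c("vignette_id", "respondent_id", "kind", "value", "low", "high", "unit")
  if (!all(req %in% names(responses))) {
    stop("`responses` must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  refreq <- c("vignette_id", "drug", "unit", "reference", "mixture")
  if (!all(refreq %in% names(references))) {
    stop("`references` must have columns: ", paste(refreq, collapse = ", "), call. = FALSE)
  }
  missing_ref <- setdiff(responses$vignette_id, references$vignette_id)
  if (length(missing_ref)) {
    stop("no reference for vignette(s): ", paste(missing_ref, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(responses) == 0) {
    return(tibble::tibble(
      vignette_id = integer(), respondent_id = character(), drug = character(),
      unit_converted = logical(), status = character(),
      candidate_value = numeric(), reference_value = numeric(),
      unit = character(), mixture = logical(), exceedance_pct = numeric(),
      exceedance_abs = numeric()
    ))
  }
  joined <- dplyr::inner_join(
    responses,
    dplyr::select(references, "vignette_id", "drug",
                  ref_unit = "unit", "reference", "mixture"),
    by = "vignette_id"
  )
  purrr::pmap_dfr(joined, function(vignette_id, respondent_id, kind, value,
                                   low, high, unit, drug, ref_unit, reference,
                                   mixture, ...) {
    cand <- normalize_response(kind, value, low, high)
    converted <- FALSE
    if (!is.na(cand) && unit != ref_unit) {
      conc <- concentrations[[drug]]
      if (is.null(conc) || is.na(conc)) {
        stop("response for vignette ", vignette_id, " is in ", unit,
             " but the reference is in ", ref_unit,
             " and no concentration is configured for ", drug, call. = FALSE)
      }
      cand <- if (unit == "mg") cand / conc else cand * conc
      converted <- TRUE
    }
    out <- evaluate_case(cand, reference, ref_unit, mixture)
    tibble::tibble(vignette_id = vignette_id, respondent_id = respondent_id,
                   drug = drug, unit_converted = converted) |>
      dplyr::bind_cols(out)
  })
}

#' Summary statistics of graded responses, per respondent
#'
#' Reproduces the reporting conventions of the evaluation design:
#' \itemize{
#'   \item rates use *provided* responses as denominator (abstentions are
#'     excluded);
#'   \item percent-exceedance mean and sample SD (n-1) are computed over
#'     unsafe cases only;
#'   \item per-drug absolute exceedances pool each case's value in its own
#'     printed unit (mg vignettes contribute mg, mL vignettes mL) unless
#'     `unit_consistent = TRUE`, which converts mL to mg through
#'     `concentrations`;
#'   \item the mixture block restricts the percent statistics to mixture
#'     vignettes.
#' }
#'
#' @param cases Output of [evaluate_responses()].
#' @param unit_consistent Convert mL absolute exceedances to mg first?
#'   Off by default, matching the pooled-unit reporting convention.
#' @param concentrations Named mg/mL vector, required when
#'   `unit_consistent = TRUE`.
#' @return List of tibbles `overall`, `per_drug`, `mixture`.
#' @export
summarize_models <- function(cases, unit_consistent = FALSE, concentrations = NULL) {
  if (unit_consistent && is.null(concentrations)) {
    stop("`unit_consistent = TRUE` needs `concentrations`", call. = FALSE)
  }
  overall <- cases |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::summarise(
      n_vignettes = dplyr::n(),
      n_provided = sum(.data$status != "missing"),
      n_unsafe = sum(.data$status == "unsafe"),
      unsafe_rate_pct = ifelse(n_provided > 0, 100 * n_unsafe / n_provided, NA_real_),
      provided_rate_pct = 100 * n_provided / n_vignettes,
      exceedance_mean_pct = mean_or_na(.data$exceedance_pct[.data$status == "unsafe"]),
      exceedance_sd_pct = sd_or_na(.data$exceedance_pct[.data$status == "unsafe"]),
      .groups = "drop"
    )
  unsafe <- dplyr::filter(cases, .data$status == "unsafe")
  if (unit_consistent) {
    unsafe <- dplyr::mutate(
      unsafe,
      exceedance_abs = ifelse(.data$unit == "mL",
                              .data$exceedance_abs * unname(concentrations[.data$drug]),
                              .data$exceedance_abs)
    )
  }
  per_drug <- unsafe |>
    dplyr::group_by(.data$respondent_id, .data$drug) |>
    dplyr::summarise(
      n_unsafe = dplyr::n(),
      abs_mean = mean_or_na(.data$exceedance_abs),
      abs_sd = sd_or_na(.data$exceedance_abs),
      .groups = "drop"
    )
  mixture <- cases |>
    dplyr::filter(.data$mixture) |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::summarise(
      n_provided = sum(.data$status != "missing"),
      n_unsafe = sum(.data$status == "unsafe"),
      exceedance_mean_pct = mean_or_na(.data$exceedance_pct[.data$status == "unsafe"]),
      exceedance_sd_pct = sd_or_na(.data$exceedance_pct[.data$status == "unsafe"]),
      .groups = "drop"
    )
  list(overall = overall, per_drug = per_drug, mixture = mixture)
}

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
sd_or_na <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)

#' Re-grade responses under alternative reference definitions
#'
#' Runs the full classification and summary once per supplied reference
#' set, e.g. references computed under the comprehensive rules and under
#' the simplified actual-weight and ideal-body-weight formulas.
#'
#' @param responses As in [evaluate_responses()].
#' @param references_by_mode Named list of reference tibbles.
#' @inheritParams evaluate_responses
#' @return Named list; each element has `cases` and `summary`.
#' @export
secondary_reference_analysis <- function(responses, references_by_mode,
                                         concentrations = NULL) {
  if (!is.list(references_by_mode) || is.null(names(references_by_mode)) ||
      any(!nzchar(names(references_by_mode)))) {
    stop("`references_by_mode` must be a named list of reference tables",
         call. = FALSE)
  }
  purrr::map(references_by_mode, function(refs) {
    cases <- evaluate_responses(responses, refs, concentrations)
    list(cases = cases, summary = summarize_models(cases))
  })
}
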