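# Synthetic clinical vignettes and simulated respondents.
#
# The generator emulates the *structure* of the evaluation questionnaire:
# adult patients varying in weight/height/age/sex, the six metabolic risk
# factors, single-agent and two-agent mixture questions, and mg vs mL
# framing. It does not reproduce any real vignette's parameters.

#' Default synthetic-panel configuration
#'
#' Sampling ranges describe a plausible adult surgical population: age
#' 18-90 y, height 145-200 cm, weight 40-140 kg, equal sexes. Organ-function
#' markers are reported only when abnormal (the corresponding risk factor is
#' present); prevalences are per patient.
#'
#' @param drugs Drug catalogue (named list of [anesthetic_spec()]).
#' @param inhibitors Inhibitor name list.
#' @return Named list of generator settings; pass to
#'   [generate_vignette_panel()] after editing any entry.
#' @export
default_panel_config <- function(drugs = default_drug_catalogue(),
                                 inhibitors = default_inhibitor_list()) {
  list(
    age_range = c(18L, 90L),
    height_range = c(145, 200),
    weight_range = c(40, 140),
    p_female = 0.5,
    p_renal = 0.10,          # GFR < 50 mL/min
    p_hepatic = 0.08,        # prothrombin time < 50%
    p_heart_failure = 0.08,  # LVEF <= 30%
    p_inhibitor = 0.15,
    p_pregnant = 0.10,       # among women aged 18-45
    p_mixture = 0.30,
    p_ml = 0.50,             # volume (mL) question framing
    mixture_proportions = c(0.3, 0.4, 0.5, 0.6, 0.7),
    drugs = drugs,
    inhibitors = inhibitors
  )
}

# Ten hand-built template vignettes guaranteeing coverage of all five CW
# branch rules, 0/1/2+ risk factors, single and mixture questions and both
# units. CW rules per template: 1,2,3,4,5,1,2,4,5,3.
panel_templates <- function(config) {
  inh <- config$inhibitors[1]
  tibble::tribble(
    ~age, ~sex, ~height_cm, ~weight_kg, ~gfr, ~prothrombin_pct, ~lvef_pct,
    ~pregnant, ~medications, ~drug1, ~drug2, ~prop1, ~question_unit,
    45L, "male",   180,   65, NA,   NA, NA, FALSE, "",  "ropivacaine",     NA,               1,   "mg",
    72L, "male",   170,   70, NA,   NA, NA, FALSE, "",  "lidocaine",       NA,               1,   "mL",
    50L, "female", 152.5, 70, NA,   NA, NA, FALSE, "",  "levobupivacaine", NA,               1,   "mg",
    75L, "male",   185,   95, 40,   NA, NA, FALSE, "",  "ropivacaine",     NA,               1,   "mL",
    32L, "female", 160,   90, NA,   NA, NA, TRUE,  "",  "levobupivacaine", NA,               1,   "mg",
    55L, "male",   178,   60, NA,   40, 25, FALSE, "",  "lidocaine",       "ropivacaine",    0.5, "mL",
    48L, "female", 165,   62, NA,   NA, NA, FALSE, "",  "levobupivacaine", "lidocaine",      0.5, "mg",
    60L, "male",   190,  110, NA,   NA, NA, FALSE, inh, "ropivacaine",     "levobupivacaine", 0.6, "mL",
    40L, "female", 158,   85, NA,   NA, NA, FALSE, "",  "lidocaine",       NA,               1,   "mg",
    80L, "female", 152.5, 69, NA,   NA, NA, FALSE, "",  "ropivacaine",     NA,               1,   "mL"
  )
}

sample_panel_row <- function(config) {
  age <- sample(config$age_range[1]:config$age_range[2], 1)
  sex <- if (stats::runif(1) < config$p_female) "female" else "male"
  height <- round(stats::runif(1, config$height_range[1], config$height_range[2]), 1)
  weight <- round(stats::runif(1, config$weight_range[1], config$weight_range[2]), 1)
  gfr <- if (stats::runif(1) < config$p_renal) round(stats::runif(1, 10, 49)) else NA_real_
  pt <- if (stats::runif(1) < config$p_hepatic) round(stats::runif(1, 20, 49)) else NA_real_
  lvef <- if (stats::runif(1) < config$p_heart_failure) round(stats::runif(1, 15, 30)) else NA_real_
  pregnant <- sex == "female" && age <= 45 && stats::runif(1) < config$p_pregnant
  meds <- if (stats::runif(1) < config$p_inhibitor) sample(config$inhibitors, 1) else ""
  drug_names <- names(config$drugs)
  mixture <- stats::runif(1) < config$p_mixture
  if (mixture) {
    picked <- sample(drug_names, 2)
    prop1 <- sample(config$mixture_proportions, 1)
  } else {
    picked <- c(sample(drug_names, 1), NA)
    prop1 <- 1
  }
  tibble::tibble(
    age = as.integer(age), sex = sex, height_cm = height, weight_kg = weight,
    gfr = gfr, prothrombin_pct = pt, lvef_pct = lvef, pregnant = pregnant,
    medications = meds, drug1 = picked[1], drug2 = picked[2], prop1 = prop1,
    question_unit = if (stats::runif(1) < config$p_ml) "mL" else "mg"
  )
}

render_narrative <- function(row) {
  sprintf(
    "A %d-year-old %s (%.0f cm, %.1f kg) is scheduled for a regional block with %s%s. What is the maximum safe dose in %s?",
    row$age, ifelse(row$sex == "male", "man", "woman"), row$height_cm,
    row$weight_kg, row$drug1,
    ifelse(is.na(row$drug2), "",
           sprintf(" mixed with %s (%.0f/%.0f toxicity split)", row$drug2,
                   100 * row$prop1, 100 * (1 - row$prop1))),
    row$question_unit
  )
}

#' Generate a synthetic vignette panel
#'
#' Builds `n` structured vignettes. For `n >= 10` the first ten are fixed
#' coverage templates that exercise all five calculation-weight branch
#' rules, patients with 0, 1 and 2+ risk factors, single-drug and mixture
#' questions, and both mg and mL framing; the remainder are sampled from
#' `config`. Panels are byte-identical for a fixed `(n, config, seed)`.
#'
#' @param n Number of vignettes, >= 1. Below 10 the coverage guarantee
#'   cannot hold and a warning is issued.
#' @param config See [default_panel_config()].
#' @param seed Integer seed; the generator never touches the caller's RNG
#'   state.
#' @return Tibble, one row per vignette: patient fields, `drug1`, `drug2`
#'   (`NA` for single-agent), `prop1`, `question_unit`, `mixture`,
#'   `narrative`.
#' @examples
#' generate_vignette_panel(10, seed = 1)
#' @export
generate_vignette_panel <- function(n, config = default_panel_config(), seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  templates <- panel_templates(config)
  if (n < 10) {
    warning("n < 10: coverage of all CW rules / risk strata not attainable; ",
            "returning the first ", n, " template vignette(s)", call. = FALSE)
    panel <- templates[seq_len(n), ]
  } else {
    extra <- if (n > 10) {
      withr::with_seed(seed, purrr::map_dfr(seq_len(n - 10), ~sample_panel_row(config)))
    } else {
      NULL
    }
    panel <- dplyr::bind_rows(templates, extra)
  }
  panel$vignette_id <- seq_len(nrow(panel))
  panel$mixture <- !is.na(panel$drug2)
  panel$narrative <- vapply(seq_len(nrow(panel)),
                            function(i) render_narrative(panel[i, ]), character(1))
  dplyr::relocate(panel, "vignette_id")
}

#' Patient record for one panel row
#'
#' @param panel Output of [generate_vignette_panel()].
#' @param i Row index.
#' @return A [patient_record()].
#' @export
panel_patient <- function(panel, i) {
  row <- panel[i, ]
  meds <- if (is.na(row$medications) || !nzchar(row$medications)) character() else
    strsplit(row$medications, ";", fixed = TRUE)[[1]]
  patient_record(age = row$age, sex = row$sex, height_cm = row$height_cm,
                 weight_kg = row$weight_kg, gfr = row$gfr,
                 prothrombin_pct = row$prothrombin_pct, lvef_pct = row$lvef_pct,
                 pregnant = row$pregnant, medications = meds)
}

#' Reference doses for a synthetic panel
#'
#' Computes each vignette's reference maximum for the drug the question
#' asks about (`drug1`; for mixtures, its share of the toxicity budget), in
#' the question's unit (mL references are floored whole millilitres).
#'
#' @param panel Output of [generate_vignette_panel()].
#' @param catalogue Drug catalogue supplying limits and concentrations.
#' @param mode Dose-rule mode, as in [max_safe_dose()].
#' @param inhibitors Inhibitor list for the risk assessment.
#' @return Reference tibble for [evaluate_responses()] (`vignette_id`,
#'   `drug`, `unit`, `reference`, `mixture`).
#' @export
compute_panel_references <- function(panel, catalogue = default_drug_catalogue(),
                                     mode = c("comprehensive", "simplified_aw",
                                              "simplified_ibw"),
                                     inhibitors = default_inhibitor_list()) {
  mode <- match.arg(mode)
  purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    patient <- panel_patient(panel, i)
    drug <- catalogue[[row$drug1]]
    if (is.null(drug)) stop("drug not in catalogue: ", row$drug1, call. = FALSE)
    res <- if (row$mixture) {
      plan <- mixture_plan(list(drug, catalogue[[row$drug2]]),
                           c(row$prop1, 1 - row$prop1))
      # heights are validated against the config range at generation time,
      # so the interactive short-stature advisory is not re-raised here
      max_safe_mixture(patient, plan, mode = mode, inhibitors = inhibitors,
                       warn = FALSE)[[1]]
    } else {
      max_safe_dose(patient, drug, mode = mode, inhibitors = inhibitors,
                    warn = FALSE)
    }
    reference <- if (row$question_unit == "mL") {
      if (is.na(res$max_ml)) stop("vignette ", row$vignette_id,
                                  " asks for mL but ", row$drug1,
                                  " has no concentration", call. = FALSE)
      as.numeric(res$max_ml)
    } else {
      res$max_mg
    }
    tibble::tibble(vignette_id = row$vignette_id, drug = row$drug1,
                   unit = row$question_unit, reference = reference,
                   mixture = row$mixture)
  })
}

#' Simulated respondent profile
#'
#' Describes how a synthetic respondent answers: probability of abstaining,
#' of phrasing the answer as a range, of flipping the unit (mg <-> mL
#' confusion), and the multiplicative bias applied to the true reference.
#' Either a lognormal bias around `bias` (spread `bias_sd` on the log
#' scale) or, when `overdose_prob` is set, a two-point bias that overdoses
#' with exactly that probability (`overdose_factor` vs `safe_factor`).
#'
#' @param profile_id Respondent identifier.
#' @param abstention_prob,range_prob,unit_confusion_prob Probabilities in
#'   \[0, 1\].
#' @param bias Central multiplicative factor, > 0 (1 = answers exactly the
#'   reference).
#' @param bias_sd Lognormal spread of the bias; 0 = deterministic.
#' @param overdose_prob Optional probability in \[0, 1\]; switches to the
#'   two-point bias model.
#' @param overdose_factor,safe_factor Factors (> 1 and <= 1) used by the
#'   two-point model.
#' @return An object of class `respondent_profile`.
#' @export
respondent_profile <- function(profile_id, abstention_prob = 0, range_prob = 0,
                               bias = 1, bias_sd = 0, overdose_prob = NULL,
                               overdose_factor = 2, safe_factor = 0.5,
                               unit_confusion_prob = 0) {
  for (p in c(abstention_prob, range_prob, unit_confusion_prob)) {
    stopifnot(is.numeric(p), length(p) == 1, p >= 0, p <= 1)
  }
  assert_positive(bias, "bias")
  stopifnot(bias_sd >= 0)
  if (!is.null(overdose_prob)) {
    stopifnot(overdose_prob >= 0, overdose_prob <= 1)
    stopifnot(overdose_factor > 1, safe_factor > 0, safe_factor <= 1)
  }
  structure(
    list(profile_id = profile_id, abstention_prob = abstention_prob,
         range_prob = range_prob, bias = bias, bias_sd = bias_sd,
         overdose_prob = overdose_prob, overdose_factor = overdose_factor,
         safe_factor = safe_factor, unit_confusion_prob = unit_confusion_prob),
    class = "respondent_profile"
  )
}

#' Simulate one respondent's answers to a panel
#'
#' Draws an answer per vignette according to the profile: abstain, or a
#' value `reference x bias draw`, optionally rendered as a range (the drawn
#' value is the low endpoint) and optionally declared in the wrong unit.
#' Ground truth is recorded per response: `truth_unsafe` is the safety
#' label in the *intended* unit before any unit flip, so downstream
#' evaluations can be checked against it.
#'
#' @param panel Output of [generate_vignette_panel()].
#' @param profile A [respondent_profile()].
#' @param references Output of [compute_panel_references()] for `panel`.
#' @param seed Integer seed for the response draws.
#' @return Response tibble in the [evaluate_responses()] schema plus
#'   `truth_unsafe` and `unit_flipped`.
#' @export
simulate_responses <- function(panel, profile, references, seed = 1L) {
  stopifnot(inherits(profile, "respondent_profile"))
  refs <- dplyr::semi_join(references, panel, by = "vignette_id")
  if (nrow(refs) != nrow(panel)) {
    stop("`references` must cover every panel vignette", call. = FALSE)
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(refs)), function(i) {
      ref <- refs[i, ]
      if (stats::runif(1) < profile$abstention_prob) {
        return(tibble::tibble(vignette_id = ref$vignette_id,
                              respondent_id = profile$profile_id,
                              kind = "abstain", value = NA_real_,
                              low = NA_real_, high = NA_real_, unit = ref$unit,
                              truth_unsafe = NA, unit_flipped = FALSE))
      }
      factor <- if (!is.null(profile$overdose_prob)) {
        if (stats::runif(1) < profile$overdose_prob) profile$overdose_factor
        else profile$safe_factor
      } else {
        profile$bias * stats::rlnorm(1, 0, max(profile$bias_sd, 0))
      }
      val <- ref$reference * factor
      truth_unsafe <- val > ref$reference
      as_range <- stats::runif(1) < profile$range_prob
      flipped <- stats::runif(1) < profile$unit_confusion_prob
      unit <- if (flipped) setdiff(c("mg", "mL"), ref$unit) else ref$unit
      tibble::tibble(
        vignette_id = ref$vignette_id, respondent_id = profile$profile_id,
        kind = if (as_range) "range" else "value",
        value = if (as_range) NA_real_ else val,
        low = if (as_range) val else NA_real_,
        high = if (as_range) val * stats::runif(1, 1.1, 1.5) else NA_real_,
        unit = unit, truth_unsafe = truth_unsafe, unit_flipped = flipped
      )
    })
  })
}
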