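#' Recompute the chatbot-evaluation summary statistics from the fixture
#'
#' Runs the full grading pipeline (normalize -> classify -> summarise) on
#' the bundled per-vignette dose table, plus the overall qualitative rating
#' per model from the bundled consensus sheet.
#'
#' @param fixtures Output of [load_fixtures()].
#' @return List: `cases` (per-case evaluations), `summary`
#'   (see [summarize_models()]) and `qualitative` (tibble respondent /
#'   overall score / label).
#' @export
compute_study_summaries <- function(fixtures = load_fixtures()) {
  cases <- evaluate_responses(fixture_responses(fixtures),
                              fixture_references(fixtures))
  qual <- purrr::map_dfr(c("gemini", "chatgpt", "copilot"), function(model) {
    cons <- likert_score(fixtures$ratings[[model]])
    ov <- overall_rating(cons)
    tibble::tibble(respondent_id = model, overall = as.integer(ov),
                   overall_label = attr(ov, "label"))
  })
  list(cases = cases, summary = summarize_models(cases), qualitative = qual)
}

# Published summary values (printed precision) used as pass/fail anchors
# by the reproduction report. These are the values being *checked*, never
# inputs to any computation.
published_statistics <- function() {
  tibble::tribble(
    ~statistic,                                ~published,
    "gemini_provided_n",                         3,
    "gemini_provided_pct",                      30,
    "gemini_mixture_exceedance_mean_pct",      140,
    "gemini_mixture_exceedance_sd_pct",        103,
    "chatgpt_provided_n",                       10,
    "chatgpt_unsafe_n",                          9,
    "chatgpt_unsafe_rate_pct",                  90,
    "chatgpt_exceedance_mean_pct",             198,
    "chatgpt_exceedance_sd_pct",               196,
    "chatgpt_lidocaine_abs_mean",              129,
    "chatgpt_lidocaine_abs_sd",                143,
    "chatgpt_levobupivacaine_abs_mean",         46,
    "chatgpt_levobupivacaine_abs_sd",           58,
    "chatgpt_ropivacaine_abs_mean",             70,
    "chatgpt_ropivacaine_abs_sd",               67,
    "copilot_provided_n",                        9,
    "copilot_unsafe_n",                          6,
    "copilot_unsafe_rate_pct",                  67,
    "copilot_exceedance_mean_pct",             217,
    "copilot_exceedance_sd_pct",               239,
    "copilot_lidocaine_abs_mean",              129,
    "copilot_lidocaine_abs_sd",                143,
    "copilot_levobupivacaine_abs_mean",         52,
    "copilot_levobupivacaine_abs_sd",           60,
    "gemini_overall_rating",                     3,
    "chatgpt_overall_rating",                    2,
    "copilot_overall_rating",                    2
  )
}

#' Reproduce the published summary statistics and report pass/fail
#'
#' Recomputes every quantitative summary statistic of the chatbot
#' evaluation from the bundled per-vignette table and the overall
#' qualitative ratings from the bundled consensus sheet, then compares each
#' against its published value after rounding to the published precision
#' (nearest integer for rates, percentages and absolute mg/mL statistics).
#'
#' @param fixtures Output of [load_fixtures()].
#' @param out_dir Optional directory; when given, the report is written as
#'   `reproduction_report.csv` and `reproduction_report.json`.
#' @return Tibble: `statistic`, `computed` (unrounded), `computed_rounded`,
#'   `published`, `pass`.
#' @examples
#' rep <- reproduce_published_results()
#' all(rep$pass)
#' @export
reproduce_published_results <- function(fixtures = load_fixtures(), out_dir = NULL) {
  res <- compute_study_summaries(fixtures)
  computed <- c(
    study_statistics_vector(res$summary),
    gemini_overall_rating = res$qualitative$overall[res$qualitative$respondent_id == "gemini"],
    chatgpt_overall_rating = res$qualitative$overall[res$qualitative$respondent_id == "chatgpt"],
    copilot_overall_rating = res$qualitative$overall[res$qualitative$respondent_id == "copilot"]
  )
  report <- published_statistics() |>
    dplyr::mutate(
      computed = unname(computed[.data$statistic]),
      computed_rounded = round_half_up(.data$computed),
      pass = .data$computed_rounded == .data$published
    ) |>
    dplyr::select("statistic", "computed", "computed_rounded", "published", "pass")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(report, file.path(out_dir, "reproduction_report.csv"))
    jsonlite::write_json(report, file.path(out_dir, "reproduction_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  report
}

# Flatten the three summary tibbles into the named statistics the
# reproduction report and the acceptance script both consume.
study_statistics_vector <- function(summary) {
  ov <- summary$overall
  pd <- summary$per_drug
  mx <- summary$mixture
  pick <- function(df, resp, col, drug = NULL) {
    rows <- df$respondent_id == resp
    if (!is.null(drug)) rows <- rows & df$drug == drug
    v <- df[[col]][rows]
    if (length(v) != 1) NA_real_ else v
  }
  c(
    gemini_provided_n = pick(ov, "gemini", "n_provided"),
    gemini_provided_pct = pick(ov, "gemini", "provided_rate_pct"),
    gemini_mixture_exceedance_mean_pct = pick(mx, "gemini", "exceedance_mean_pct"),
    gemini_mixture_exceedance_sd_pct = pick(mx, "gemini", "exceedance_sd_pct"),
    chatgpt_provided_n = pick(ov, "chatgpt", "n_provided"),
    chatgpt_unsafe_n = pick(ov, "chatgpt", "n_unsafe"),
    chatgpt_unsafe_rate_pct = pick(ov, "chatgpt", "unsafe_rate_pct"),
    chatgpt_exceedance_mean_pct = pick(ov, "chatgpt", "exceedance_mean_pct"),
    chatgpt_exceedance_sd_pct = pick(ov, "chatgpt", "exceedance_sd_pct"),
    chatgpt_lidocaine_abs_mean = pick(pd, "chatgpt", "abs_mean", "lidocaine"),
    chatgpt_lidocaine_abs_sd = pick(pd, "chatgpt", "abs_sd", "lidocaine"),
    chatgpt_levobupivacaine_abs_mean = pick(pd, "chatgpt", "abs_mean", "levobupivacaine"),
    chatgpt_levobupivacaine_abs_sd = pick(pd, "chatgpt", "abs_sd", "levobupivacaine"),
    chatgpt_ropivacaine_abs_mean = pick(pd, "chatgpt", "abs_mean", "ropivacaine"),
    chatgpt_ropivacaine_abs_sd = pick(pd, "chatgpt", "abs_sd", "ropivacaine"),
    copilot_provided_n = pick(ov, "copilot", "n_provided"),
    copilot_unsafe_n = pick(ov, "copilot", "n_unsafe"),
    copilot_unsafe_rate_pct = pick(ov, "copilot", "unsafe_rate_pct"),
    copilot_exceedance_mean_pct = pick(ov, "copilot", "exceedance_mean_pct"),
    copilot_exceedance_sd_pct = pick(ov, "copilot", "exceedance_sd_pct"),
    copilot_lidocaine_abs_mean = pick(pd, "copilot", "abs_mean", "lidocaine"),
    copilot_lidocaine_abs_sd = pick(pd, "copilot", "abs_sd", "lidocaine"),
    copilot_levobupivacaine_abs_mean = pick(pd, "copilot", "abs_mean", "levobupivacaine"),
    copilot_levobupivacaine_abs_sd = pick(pd, "copilot", "abs_sd", "levobupivacaine")
  )
}
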