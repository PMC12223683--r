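#' Run the full synthetic evaluation pipeline
#'
#' simulate -> compute references -> grade -> summarise, writing all
#' artifacts (panel, references, responses, case evaluations, summary JSON
#' and a run log with seed and file checksums) into `out_dir`. A fixed
#' `(n, config, profiles, seed)` reproduces byte-identical artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param n Panel size.
#' @param profiles List of [respondent_profile()] objects; defaults to an
#'   exact-reference respondent, an overdose-prone one and a frequent
#'   abstainer.
#' @param config Generator configuration, see [default_panel_config()].
#' @param mode Dose-rule mode for the references.
#' @param seed Master seed; per-respondent response seeds are derived from
#'   it.
#' @param quiet Suppress the console note.
#' @return (Invisibly) list with `panel`, `references`, `responses`,
#'   `cases`, `summary` and the output paths.
#' @export
run_pipeline <- function(out_dir, n = 10,
                         profiles = default_profiles(),
                         config = default_panel_config(),
                         mode = c("comprehensive", "simplified_aw", "simplified_ibw"),
                         seed = 1L, quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.list(profiles), length(profiles) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  panel <- generate_vignette_panel(n, config, seed = seed)
  references <- compute_panel_references(panel, catalogue = config$drugs,
                                         mode = mode,
                                         inhibitors = config$inhibitors)
  responses <- purrr::map2_dfr(profiles, seq_along(profiles), function(p, i) {
    simulate_responses(panel, p, references, seed = seed + i)
  })
  concs <- vapply(config$drugs, `[[`, numeric(1), "concentration")
  cases <- evaluate_responses(responses, references, concentrations = concs)
  summary <- summarize_models(cases)

  paths <- c(panel = file.path(out_dir, "panel.csv"),
             references = file.path(out_dir, "references.csv"),
             responses = file.path(out_dir, "responses.csv"),
             cases = file.path(out_dir, "case_evaluations.csv"),
             summary = file.path(out_dir, "summary.json"))
  readr::write_csv(panel, paths[["panel"]])
  readr::write_csv(references, paths[["references"]])
  readr::write_csv(responses, paths[["responses"]])
  readr::write_csv(cases, paths[["cases"]])
  jsonlite::write_json(summary, paths[["summary"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    "RESEARCH USE ONLY - not a medical device; do not use for clinical dosing.",
    sprintf("ladose %s | R %s", as.character(utils::packageVersion("ladose")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d | n: %d | mode: %s", seed, n, mode),
    sprintf("profiles: %s",
            paste(vapply(profiles, `[[`, character(1), "profile_id"), collapse = ", ")),
    "artifact md5:",
    paste(" ", basename(paths), unname(tools::md5sum(paths)))
  ), file.path(out_dir, "run_log.txt"))

  if (!quiet) {
    message("pipeline artifacts written to ", normalizePath(out_dir),
            " (research use only)")
  }
  invisible(list(panel = panel, references = references, responses = responses,
                 cases = cases, summary = summary, paths = paths))
}

#' Default simulated-respondent panel
#'
#' Three contrasting behaviours: `exact` answers every reference exactly,
#' `overdose_prone` doubles half its answers and abstains occasionally,
#' `cautious_abstainer` abstains 70% of the time and underdoses otherwise.
#'
#' @return List of [respondent_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    respondent_profile("exact"),
    respondent_profile("overdose_prone", abstention_prob = 0.1,
                       range_prob = 0.2, overdose_prob = 0.5),
    respondent_profile("cautious_abstainer", abstention_prob = 0.7, bias = 0.8)
  )
}
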