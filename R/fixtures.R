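# Bundled evaluation dataset: per-vignette doses recommended by three AI
# chatbots alongside the rule-based reference maxima, and the two-reviewer
# consensus quality ratings. Transcribed once from the published tables and
# guarded by checksums so a silent edit cannot skew a reproduction run.

.fixture_md5 <- c(
  ai_model_doses.csv   = "73eac62cda5c5f1d0677c2e8618d697e",
  ai_model_ratings.csv = "566fb48987bc9c3de32c949453405ca0"
)

fixture_path <- function(file) {
  system.file("extdata", file, package = "ladose", mustWork = TRUE)
}

#' Load the bundled chatbot-evaluation fixtures
#'
#' Returns the 10-vignette dose table (drug, unit, rule-based reference,
#' mixture flag, and the value each of the three chatbots gave, `NA` for an
#' abstention) and the 8-criterion consensus quality ratings. Files are
#' checksummed; a mismatch is a hard error.
#'
#' @param check Verify the MD5 checksums (default `TRUE`).
#' @return List with tibbles `doses` and `ratings`.
#' @examples
#' fx <- load_fixtures()
#' fx$doses
#' @export
load_fixtures <- function(check = TRUE) {
  paths <- vapply(names(.fixture_md5), fixture_path, character(1))
  if (check) {
    got <- unname(tools::md5sum(paths))
    bad <- got != unname(.fixture_md5)
    if (any(bad)) {
      stop("fixture checksum mismatch: ",
           paste(names(.fixture_md5)[bad], collapse = ", "),
           " - the bundled data have been altered", call. = FALSE)
    }
  }
  doses <- readr::read_csv(
    paths[["ai_model_doses.csv"]],
    col_types = readr::cols(
      vignette_id = readr::col_integer(), drug = readr::col_character(),
      unit = readr::col_character(), reference = readr::col_double(),
      mixture = readr::col_character(), gemini = readr::col_double(),
      chatgpt = readr::col_double(), copilot = readr::col_double()
    )
  )
  doses$mixture <- doses$mixture == "yes"
  ratings <- readr::read_csv(
    paths[["ai_model_ratings.csv"]],
    col_types = readr::cols(.default = readr::col_character())
  )
  list(doses = doses, ratings = ratings)
}

#' Reference table from the bundled dose fixture
#'
#' @param fixtures Output of [load_fixtures()].
#' @return Tibble with `vignette_id`, `drug`, `unit`, `reference`, `mixture`,
#'   directly usable by [evaluate_responses()].
#' @export
fixture_references <- function(fixtures = load_fixtures()) {
  dplyr::select(fixtures$doses, "vignette_id", "drug", "unit", "reference", "mixture")
}

#' Long-format responses from the bundled dose fixture
#'
#' Pivots the three chatbot columns into the response schema used by
#' [evaluate_responses()]. Fixture values are already normalized (the low
#' endpoint of any suggested range); `NA` cells become abstentions.
#'
#' @param fixtures Output of [load_fixtures()].
#' @return Response tibble (`vignette_id`, `respondent_id`, `kind`, `value`,
#'   `low`, `high`, `unit`).
#' @export
fixture_responses <- function(fixtures = load_fixtures()) {
  fixtures$doses |>
    tidyr::pivot_longer(cols = c("gemini", "chatgpt", "copilot"),
                        names_to = "respondent_id", values_to = "value") |>
    dplyr::transmute(
      .data$vignette_id,
      .data$respondent_id,
      kind = ifelse(is.na(.data$value), "abstain", "value"),
      value = .data$value,
      low = NA_real_, high = NA_real_,
      unit = .data$unit
    )
}
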