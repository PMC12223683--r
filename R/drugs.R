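#' Local anesthetic definition
#'
#' @param name Drug name (lower-cased for lookup).
#' @param dose_limit Maximum dose per kilogram of calculation weight, mg/kg.
#' @param concentration Solution concentration in mg/mL, or `NA` when only
#'   mg answers are needed.
#'
#' @return An object of class `anesthetic_spec`.
#' @examples
#' anesthetic_spec("ropivacaine", dose_limit = 3, concentration = 7.5)
#' @export
anesthetic_spec <- function(name, dose_limit, concentration = NA_real_) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  assert_scalar_number(dose_limit, "dose_limit")
  assert_positive(dose_limit, "dose_limit")
  if (!is.na(concentration)) {
    assert_scalar_number(concentration, "concentration")
    assert_positive(concentration, "concentration")
  }
  structure(
    list(name = tolower(name), dose_limit = as.numeric(dose_limit),
         concentration = as.numeric(concentration)),
    class = "anesthetic_spec"
  )
}

#' @export
print.anesthetic_spec <- function(x, ...) {
  cat(sprintf("<anesthetic_spec> %s: %.3g mg/kg%s\n", x$name, x$dose_limit,
              if (is.na(x$concentration)) "" else sprintf(", %.3g mg/mL", x$concentration)))
  invisible(x)
}

#' Default drug catalogue
#'
#' Reads the per-kg dose limits and default concentrations from the bundled
#' YAML configuration (or any file with the same layout). The limits are
#' documented literature defaults, deliberately kept in an editable config
#' rather than hard-coded: they are an input to the calculator, not a
#' property of it.
#'
#' @param path Path to a catalogue YAML; defaults to the bundled file.
#' @return Named list of [anesthetic_spec()] objects.
#' @export
default_drug_catalogue <- function(path = NULL) {
  cfg <- read_drug_config(path)
  specs <- lapply(names(cfg$drugs), function(nm) {
    d <- cfg$drugs[[nm]]
    anesthetic_spec(nm, d$dose_limit, d$concentration %||% NA_real_)
  })
  stats::setNames(specs, names(cfg$drugs))
}

#' Default CYP1A2/3A inhibitor list
#'
#' @inheritParams default_drug_catalogue
#' @return Character vector of drug names, lower-cased.
#' @export
default_inhibitor_list <- function(path = NULL) {
  tolower(unlist(read_drug_config(path)$inhibitors))
}

read_drug_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_catalogue.yaml", package = "ladose",
                        mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$drugs) || !length(cfg$drugs)) {
    stop("drug catalogue config has no `drugs` section: ", path, call. = FALSE)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mixture plan for two (or more) co-administered anesthetics
#'
#' Each component is assigned a share of a common toxicity budget; shares
#' must be strictly positive and sum to one (fractional additive toxicity).
#'
#' @param drugs List of [anesthetic_spec()] objects with distinct names.
#' @param proportions Numeric vector, same length, > 0, summing to 1.
#' @return An object of class `mixture_plan`.
#' @examples
#' cat <- default_drug_catalogue()
#' mixture_plan(list(cat$lidocaine, cat$ropivacaine), c(0.5, 0.5))
#' @export
mixture_plan <- function(drugs, proportions) {
  stopifnot(is.list(drugs), length(drugs) >= 1)
  if (!all(vapply(drugs, inherits, logical(1), "anesthetic_spec"))) {
    stop("`drugs` must be a list of anesthetic_spec objects", call. = FALSE)
  }
  nms <- vapply(drugs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("mixture components must be distinct drugs", call. = FALSE)
  assert_positive(proportions, "proportions")
  if (length(proportions) != length(drugs)) {
    stop("`proportions` must match `drugs` in length", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("mixture proportions must sum to 1", call. = FALSE)
  }
  structure(list(drugs = drugs, proportions = as.numeric(proportions)),
            class = "mixture_plan")
}
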