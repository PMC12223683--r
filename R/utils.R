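# internal helpers

round_half_up <- function(x) floor(x + 0.5)

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be positive and finite", call. = FALSE)
  }
  invisible(x)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

match_sex <- function(sex) {
  if (!is.character(sex)) stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  out <- match.arg(tolower(sex), c("male", "female"), several.ok = TRUE)
  if (length(out) != length(sex)) {
    out <- vapply(tolower(sex), function(s) match.arg(s, c("male", "female")), character(1))
  }
  unname(out)
}
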