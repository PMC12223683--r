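# Independent brute-force oracles. These are literal, scalar transcriptions
# of the rule statements, kept deliberately separate from the vectorised
# implementations they check.

# Calculation weight: one sentence per branch, then the 70 kg cap.
oracle_cw <- function(aw, ibw, bmi) {
  cw <- if (aw <= 70 && bmi < 30 && ibw > aw) {
    aw
  } else if (aw <= 70 && bmi < 30 && ibw <= aw) {
    ibw
  } else if (aw <= 70 && bmi >= 30) {
    ibw
  } else if (aw > 70 && ibw > 70) {
    70
  } else if (aw > 70 && ibw <= 70) {
    ibw
  } else {
    stop("no branch rule fired")
  }
  min(cw, 70)
}

# How many of the five branch conditions hold for one input point.
oracle_cw_rules_firing <- function(aw, ibw, bmi) {
  sum(c(aw <= 70 && bmi < 30 && ibw > aw,
        aw <= 70 && bmi < 30 && ibw <= aw,
        aw <= 70 && bmi >= 30,
        aw > 70 && ibw > 70,
        aw > 70 && ibw <= 70))
}

# Literal re-count of an evaluation panel: strict comparison, abstentions
# excluded from the denominator.
oracle_recount <- function(candidates, references) {
  n_provided <- 0L; n_unsafe <- 0L
  for (i in seq_along(candidates)) {
    if (is.na(candidates[i])) next
    n_provided <- n_provided + 1L
    if (candidates[i] > references[i]) n_unsafe <- n_unsafe + 1L
  }
  list(n_provided = n_provided, n_unsafe = n_unsafe)
}

# Spreadsheet-style Cronbach alpha: explicit sample variances, raters as
# the k components scored across items.
oracle_alpha <- function(m) {
  svar <- function(x) {
    mu <- sum(x) / length(x)
    sum((x - mu)^2) / (length(x) - 1)
  }
  k <- nrow(m)
  totals <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) totals[j] <- sum(m[, j])
  rater_sum <- 0
  for (i in seq_len(k)) rater_sum <- rater_sum + svar(m[i, ])
  k / (k - 1) * (1 - rater_sum / svar(totals))
}

# A no-risk-factor patient whose calculation weight is exactly the cap.
cap_patient <- function() {
  patient_record(age = 45, sex = "male", height_cm = 178, weight_kg = 70)
}
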