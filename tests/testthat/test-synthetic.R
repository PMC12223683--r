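test_that("panels are byte-identical under a fixed seed and differ across seeds", {
  p1 <- generate_vignette_panel(25, seed = 4)
  p2 <- generate_vignette_panel(25, seed = 4)
  expect_identical(p1, p2)
  p3 <- generate_vignette_panel(25, seed = 5)
  expect_false(identical(p1, p3))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_vignette_panel(12, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a 10-vignette panel covers all CW rules, risk strata, mixtures and units", {
  panel <- generate_vignette_panel(10, seed = 1)
  expect_equal(nrow(panel), 10)
  rules <- vapply(seq_len(10), function(i)
    anthropometrics(panel_patient(panel, i), warn = FALSE)$cw_rule, integer(1))
  expect_setequal(rules, 1:5)
  n_risk <- vapply(seq_len(10), function(i)
    assess_risk_factors(panel_patient(panel, i))$n_factors, numeric(1))
  expect_true(any(n_risk == 0) && any(n_risk == 1) && any(n_risk >= 2))
  expect_true(any(panel$mixture) && any(!panel$mixture))
  expect_setequal(unique(panel$question_unit), c("mg", "mL"))
  expect_true(all(nzchar(panel$narrative)))
})

test_that("n below 10 degrades to a best-effort panel with a warning", {
  expect_warning(small <- generate_vignette_panel(3, seed = 1), "coverage")
  expect_equal(nrow(small), 3)
})

test_that("sampled risk-factor prevalence tracks the configured rate", {
  config <- default_panel_config()
  panel <- generate_vignette_panel(1010, config, seed = 2026)
  tail_rows <- panel[-(1:10), ] # the sampled (non-template) vignettes
  n <- nrow(tail_rows)
  for (fld in c("gfr", "prothrombin_pct", "lvef_pct")) {
    p_cfg <- switch(fld, gfr = config$p_renal, prothrombin_pct = config$p_hepatic,
                    lvef_pct = config$p_heart_failure)
    rate <- mean(!is.na(tail_rows[[fld]]))
    expect_lt(abs(rate - p_cfg), 3 * sqrt(p_cfg * (1 - p_cfg) / n))
  }
  expect_lt(abs(mean(tail_rows$mixture) - config$p_mixture),
            3 * sqrt(config$p_mixture * (1 - config$p_mixture) / n))
})

test_that("panel references honour the question unit and the mixture budget", {
  panel <- generate_vignette_panel(10, seed = 3)
  refs <- compute_panel_references(panel)
  expect_equal(refs$vignette_id, panel$vignette_id)
  ml <- refs$reference[refs$unit == "mL"]
  expect_true(all(ml == floor(ml))) # volumes are floored integers
  expect_true(all(refs$reference > 0))
  # a mixture vignette's reference is its share of the stand-alone maximum
  i <- which(panel$mixture)[1]
  catalogue <- default_drug_catalogue()
  standalone <- max_safe_dose(panel_patient(panel, i),
                              catalogue[[panel$drug1[i]]], warn = FALSE)
  expected_mg <- panel$prop1[i] * standalone$max_mg
  expected <- if (panel$question_unit[i] == "mL") {
    mg_to_max_volume(expected_mg, catalogue[[panel$drug1[i]]]$concentration)
  } else expected_mg
  expect_equal(refs$reference[i], as.numeric(expected))
})

test_that("an exact-reference respondent is graded 0% unsafe, a doubling one 100% at +100%", {
  panel <- generate_vignette_panel(10, seed = 6)
  refs <- compute_panel_references(panel)
  exact <- simulate_responses(panel, respondent_profile("exact"), refs, seed = 1)
  cases <- evaluate_responses(exact, refs)
  expect_true(all(cases$status == "safe"))

  doubler <- simulate_responses(panel, respondent_profile("double", bias = 2),
                                refs, seed = 1)
  dcases <- evaluate_responses(doubler, refs)
  expect_true(all(dcases$status == "unsafe"))
  expect_true(all(abs(dcases$exceedance_pct - 100) < 1e-9))
})

test_that("abstention frequency follows the profile", {
  panel <- generate_vignette_panel(1000, seed = 8)
  refs <- compute_panel_references(panel)
  prof <- respondent_profile("shy", abstention_prob = 0.7)
  resp <- simulate_responses(panel, prof, refs, seed = 2)
  provided <- mean(resp$kind != "abstain")
  expect_lt(abs(provided - 0.3), 3 * sqrt(0.7 * 0.3 / 1000))
})

test_that("generator ground-truth labels agree with the evaluation module", {
  panel <- generate_vignette_panel(300, seed = 10)
  refs <- compute_panel_references(panel)
  prof <- respondent_profile("mixed", overdose_prob = 0.4, range_prob = 0.3)
  resp <- simulate_responses(panel, prof, refs, seed = 11)
  cases <- evaluate_responses(resp, refs)
  merged <- dplyr::inner_join(resp, cases, by = c("vignette_id", "respondent_id"))
  provided <- dplyr::filter(merged, kind != "abstain")
  expect_equal(provided$status == "unsafe", provided$truth_unsafe)
})

test_that("with unit confusion, label mismatches occur only on flipped responses", {
  panel <- generate_vignette_panel(400, seed = 12)
  refs <- compute_panel_references(panel)
  prof <- respondent_profile("confused", overdose_prob = 0.4,
                             unit_confusion_prob = 0.3)
  resp <- simulate_responses(panel, prof, refs, seed = 13)
  expect_gt(sum(resp$unit_flipped), 0)
  concs <- vapply(default_drug_catalogue(), `[[`, numeric(1), "concentration")
  cases <- evaluate_responses(resp, refs, concentrations = concs)
  merged <- dplyr::inner_join(resp, cases, by = c("vignette_id", "respondent_id"))
  provided <- dplyr::filter(merged, kind != "abstain")
  mismatch <- (provided$status == "unsafe") != provided$truth_unsafe
  expect_true(all(provided$unit_flipped[mismatch]))
})

test_that("evaluated unsafe rate recovers the profile's overdose probability", {
  p_true <- 0.3
  panel <- generate_vignette_panel(1000, seed = 14)
  refs <- compute_panel_references(panel)
  prof <- respondent_profile("calibrated", overdose_prob = p_true)
  resp <- simulate_responses(panel, prof, refs, seed = 15)
  s <- summarize_models(evaluate_responses(resp, refs))
  rate <- s$overall$unsafe_rate_pct / 100
  n <- s$overall$n_provided
  expect_lt(abs(rate - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("respondent profiles validate their probabilities and factors", {
  expect_error(respondent_profile("x", abstention_prob = 1.2))
  expect_error(respondent_profile("x", bias = -1), "positive")
  expect_error(respondent_profile("x", overdose_prob = 0.5, overdose_factor = 0.9))
})
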