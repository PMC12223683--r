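# small hand-built response panel used by several blocks
toy_references <- tibble::tibble(
  vignette_id = 1:4,
  drug = c("lidocaine", "lidocaine", "ropivacaine", "ropivacaine"),
  unit = c("mg", "mL", "mg", "mL"),
  reference = c(100, 10, 200, 20),
  mixture = c(FALSE, TRUE, FALSE, TRUE)
)

toy_responses <- tibble::tibble(
  vignette_id = c(1:4, 1:4),
  respondent_id = rep(c("a", "b"), each = 4),
  kind = c("value", "range", "abstain", "value", "value", "value", "value", "value"),
  value = c(150, NA, NA, 20, 100, 9, 300, 25),
  low = c(NA, 15, NA, NA, NA, NA, NA, NA),
  high = c(NA, 22, NA, NA, NA, NA, NA, NA),
  unit = c("mg", "mL", "mg", "mL", "mg", "mL", "mg", "mL")
)

test_that("responses normalize to a single value: itself, low endpoint, or missing", {
  expect_equal(normalize_response("value", 270), 270)
  expect_equal(normalize_response("range", low = 15, high = 22), 15)
  expect_true(is.na(normalize_response("abstain")))
  expect_error(normalize_response("value", -3), "positive")
  expect_error(normalize_response("range", low = 22, high = 15), "low <= high")
})

test_that("case grading is strict with percent and absolute exceedance", {
  unsafe <- evaluate_case(240, 110, "mg")
  expect_equal(unsafe$status, "unsafe")
  expect_equal(unsafe$exceedance_pct, (240 - 110) / 110 * 100)
  expect_equal(round(unsafe$exceedance_pct, 1), 118.2)
  expect_equal(unsafe$exceedance_abs, 130)

  safe <- evaluate_case(16, 29, "mL")
  expect_equal(safe$status, "safe")
  expect_true(is.na(safe$exceedance_pct) && is.na(safe$exceedance_abs))

  boundary <- evaluate_case(82.5, 82.5, "mg")
  expect_equal(boundary$status, "safe")

  missing <- evaluate_case(NA, 82.5, "mg")
  expect_equal(missing$status, "missing")
})

test_that("panel classification matches a literal brute-force recount", {
  cases <- evaluate_responses(toy_responses, toy_references)
  for (resp in c("a", "b")) {
    sub <- dplyr::filter(cases, respondent_id == resp)
    counted <- oracle_recount(sub$candidate_value, sub$reference_value)
    expect_equal(sum(sub$status != "missing"), counted$n_provided)
    expect_equal(sum(sub$status == "unsafe"), counted$n_unsafe)
  }
  # respondent a: 150>100 unsafe, 15>10 unsafe, abstain, 20<=20 safe
  a <- dplyr::filter(cases, respondent_id == "a")
  expect_equal(a$status, c("unsafe", "unsafe", "missing", "safe"))
})

test_that("summaries use provided-response denominators and n-1 standard deviations", {
  cases <- evaluate_responses(toy_responses, toy_references)
  s <- summarize_models(cases)
  a <- dplyr::filter(s$overall, respondent_id == "a")
  expect_equal(a$n_vignettes, 4L)
  expect_equal(a$n_provided, 3L)
  expect_equal(a$n_unsafe, 2L)
  expect_equal(a$unsafe_rate_pct, 2 / 3 * 100)
  expect_equal(a$exceedance_mean_pct, mean(c(50, 50)))
  expect_equal(a$exceedance_sd_pct, stats::sd(c(50, 50)))
  # single unsafe case: mean defined, sample SD absent
  b <- dplyr::filter(s$overall, respondent_id == "b")
  expect_equal(b$n_unsafe, 2L)
  one <- summarize_models(dplyr::filter(cases, respondent_id == "b",
                                        vignette_id %in% c(1, 3)))
  expect_equal(one$overall$n_unsafe, 1L)
  expect_false(is.na(one$overall$exceedance_mean_pct))
  expect_true(is.na(one$overall$exceedance_sd_pct))
  # zero unsafe cases: exceedance fields absent, not zero
  none <- summarize_models(dplyr::filter(cases, status == "safe"))
  expect_true(all(is.na(none$overall$exceedance_mean_pct)))
})

test_that("per-drug absolute statistics pool each case's printed unit; a unit-consistent mode converts", {
  cases <- evaluate_responses(toy_responses, toy_references)
  s <- summarize_models(cases)
  a_lido <- dplyr::filter(s$per_drug, respondent_id == "a", drug == "lidocaine")
  expect_equal(a_lido$abs_mean, mean(c(50, 5))) # 50 mg pooled with 5 mL
  s2 <- summarize_models(cases, unit_consistent = TRUE,
                         concentrations = c(lidocaine = 10, ropivacaine = 7.5))
  a_lido2 <- dplyr::filter(s2$per_drug, respondent_id == "a", drug == "lidocaine")
  expect_equal(a_lido2$abs_mean, mean(c(50, 5 * 10)))
})

test_that("mixture statistics are restricted to mixture vignettes", {
  cases <- evaluate_responses(toy_responses, toy_references)
  s <- summarize_models(cases)
  a_mix <- dplyr::filter(s$mixture, respondent_id == "a")
  expect_equal(a_mix$n_unsafe, 1L) # only vignette 2 of the two mixtures
  expect_equal(a_mix$exceedance_mean_pct, 50)
})

test_that("unsafe rate is invariant under a common unit conversion", {
  conc <- 7.5
  refs_ml <- dplyr::mutate(toy_references, unit = "mL", reference = reference / conc)
  resp_ml <- dplyr::mutate(toy_responses, unit = "mL",
                           value = value / conc, low = low / conc, high = high / conc)
  s_orig <- summarize_models(evaluate_responses(toy_responses, toy_references))
  s_conv <- summarize_models(evaluate_responses(resp_ml, refs_ml))
  expect_equal(s_conv$overall$unsafe_rate_pct, s_orig$overall$unsafe_rate_pct)
  expect_equal(s_conv$overall$exceedance_mean_pct, s_orig$overall$exceedance_mean_pct)
})

test_that("removing a safe case shifts rates but never the exceedance moments", {
  cases <- evaluate_responses(toy_responses, toy_references)
  b_all <- summarize_models(dplyr::filter(cases, respondent_id == "b"))
  b_cut <- summarize_models(dplyr::filter(cases, respondent_id == "b",
                                          !(status == "safe" & vignette_id == 2)))
  expect_equal(b_cut$overall$n_provided, b_all$overall$n_provided - 1L)
  expect_gt(b_cut$overall$unsafe_rate_pct, b_all$overall$unsafe_rate_pct)
  expect_equal(b_cut$overall$exceedance_mean_pct, b_all$overall$exceedance_mean_pct)
  expect_equal(b_cut$overall$exceedance_sd_pct, b_all$overall$exceedance_sd_pct)
})

test_that("mismatched units are converted through the concentration or rejected", {
  resp <- tibble::tibble(vignette_id = 1L, respondent_id = "a", kind = "value",
                         value = 12, low = NA_real_, high = NA_real_, unit = "mL")
  refs <- toy_references[1, ] # reference 100 mg lidocaine
  case <- evaluate_responses(resp, refs, concentrations = c(lidocaine = 10))
  expect_true(case$unit_converted)
  expect_equal(case$candidate_value, 120) # 12 mL x 10 mg/mL
  expect_equal(case$status, "unsafe")
  expect_error(evaluate_responses(resp, refs), "concentration")
  expect_error(evaluate_responses(dplyr::mutate(resp, vignette_id = 99L), refs),
               "no reference")
})

test_that("secondary reference sets re-grade the same responses", {
  refs_by_mode <- list(
    comprehensive = toy_references,
    identical = toy_references,
    stricter = dplyr::mutate(toy_references, reference = reference * 0.5)
  )
  out <- secondary_reference_analysis(toy_responses, refs_by_mode)
  expect_named(out, c("comprehensive", "identical", "stricter"))
  expect_equal(out$identical$summary, out$comprehensive$summary)
  expect_true(all(out$stricter$summary$overall$unsafe_rate_pct >=
                  out$comprehensive$summary$overall$unsafe_rate_pct))
  # hand count under the stricter set, respondent a: 150>50, 15>5, -, 20>10
  a <- dplyr::filter(out$stricter$summary$overall, respondent_id == "a")
  expect_equal(a$n_unsafe, 3L)
  expect_error(secondary_reference_analysis(toy_responses, list(toy_references)),
               "named")
})
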