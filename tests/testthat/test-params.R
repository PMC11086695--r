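test_that("default parameters carry the published program values", {
  co <- cohort_params()
  expect_identical(co$initial_unscreened, 215000)
  expect_identical(co$annual_growth, 0.05)
  expect_identical(co$horizon, 5L)
  expect_identical(co$uninsured_fraction, 0.39)

  b <- behavior_params()
  expect_identical(b$first_return_rate, 0.19)
  expect_identical(b$reminder_fraction, 0.83)
  expect_identical(b$positivity_initial, 0.06)
  expect_identical(b$positivity_later, 0.05)
  expect_identical(b$crc_detection_rate, 0.045)
  expect_identical(b$adenoma_detection_rate, 0.39)
  expect_identical(b$optout_rate, 0)
  expect_identical(b$postcard_return_rate, 0)

  u <- unit_costs()
  expect_identical(u$mailer, 6.73)
  expect_identical(u$reminder_letter, 1.15)
  expect_identical(u$text_setup, 78.95)
  expect_identical(u$results_letter, 1.15)
  expect_identical(u$postcard_processing, 3.96)
  expect_identical(u$reply_mail_annual, 275)
  expect_identical(u$fit_processing, 20)
  expect_identical(u$update_result, 0.97)
  expect_identical(u$positive_call, 3.96)
  expect_identical(u$navigator_wage, 39.59)
  expect_identical(u$clerical_wage, 29.22)
  expect_identical(u$colonoscopy, 1800)

  org_tab <- list(
    centralized = c(0.15, 0.05, 0.90, 0.65, 20, 18, 1, 1),
    hybrid = c(0.20, 0.075, 0.90, 0.70, 20, 15, 1, 7),
    regional = c(0.24, 0.10, 0.95, 0.70, 23, 15, 7, 7)
  )
  for (nm in names(org_tab)) {
    o <- org_config(nm)
    got <- c(o$indirect_rate, o$startup_rate, o$unspoiled_rate,
             o$navigation_success, o$fit_fee, o$navigation_minutes,
             o$n_mailing_sites, o$n_navigation_sites)
    expect_equal(got, org_tab[[nm]], info = nm)
  }
})

test_that("validation is total: out-of-range values are rejected by field name", {
  cases <- list(
    list(function() cohort_params(uninsured_fraction = 1.5), "uninsured_fraction"),
    list(function() cohort_params(initial_unscreened = -1), "initial_unscreened"),
    list(function() cohort_params(annual_growth = -0.1), "annual_growth"),
    list(function() cohort_params(horizon = 0), "horizon"),
    list(function() behavior_params(first_return_rate = 1.2), "first_return_rate"),
    list(function() behavior_params(positivity_initial = -0.1), "positivity_initial"),
    list(function() behavior_params(crc_detection_rate = 2), "crc_detection_rate"),
    list(function() unit_costs(mailer = -6.73), "mailer"),
    list(function() unit_costs(colonoscopy = -1), "colonoscopy"),
    list(function() org_config("hybrid", indirect_rate = 1.3), "indirect_rate"),
    list(function() org_config("hybrid", navigation_success = -0.2), "navigation_success"),
    list(function() org_config("hybrid", n_mailing_sites = 0), "n_mailing_sites"),
    list(function() prevention_coefficients(prevented_per_unit = -1), "prevented_per_unit"),
    list(function() model_config(discount_rate = 1.5), "discount_rate")
  )
  for (case in cases) expect_error(case[[1]](), case[[2]])
  expect_error(model_config(strategy = "sometimes"), "strategy")
  expect_error(behavior_params(conditional_return = c(maybe_1 = 0.5)),
               "conditional_return")
})

test_that("timed staff tasks reprice to the published unit costs", {
  # navigation: 15 min regional/hybrid, 18 min centralized
  expect_identical(labor_cost(39.59, 15), 9.90)
  expect_equal(labor_cost(39.59, 18), 11.88, tolerance = 1e-12)
  # unrounded value feeds the cost model
  expect_equal(labor_cost(39.59, 18, round_cents = FALSE), 11.877,
               tolerance = 1e-12)
})

test_that("conditional-return table is well-formed and keyed correctly", {
  tab <- default_conditional_return()
  expect_true(all(grepl("^(yes|no)_[0-9]+$", names(tab))))
  expect_true(all(tab >= 0 & tab <= 1))
  # never-returners respond below the published 3% bound
  expect_lt(tab[["no_0"]], 0.03)
  # behavioral ordering: recent returners above lapsed above never
  expect_gte(tab[["yes_1"]], tab[["no_1"]])
  expect_gt(tab[["no_1"]], tab[["no_0"]])
})
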