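test_that("cohort growth produces the expected entrant streams", {
  co <- cohort_params()
  expect_equal(new_entrants(co, 2), 10750)
  # geometric growth: successive entrant cohorts grow by the growth rate
  expect_equal(new_entrants(co, 3) / new_entrants(co, 2), 1.05)
  expect_equal(new_entrants(co, 5), 215000 * 0.05 * 1.05^3)

  flat <- cohort_params(annual_growth = 0)
  for (t in 2:5) expect_identical(new_entrants(flat, t), 0)

  simple <- cohort_params(growth_compounding = FALSE)
  expect_equal(new_entrants(simple, 2), new_entrants(simple, 5))
  expect_error(new_entrants(co, 1))
})

test_that("mailing rules implement the three outreach strategies", {
  # returned at least once: any R in history qualifies
  expect_true(mailing_eligible("NR", "at_least_once"))
  expect_false(mailing_eligible("NN", "at_least_once"))
  # previous year: last outcome decides
  expect_false(mailing_eligible("RN", "previous_year"))
  expect_true(mailing_eligible("NR", "previous_year"))
  # new entrants always mailed, everyone always mailed
  for (s in outreach_strategies()) expect_true(mailing_eligible("", s))
  expect_true(mailing_eligible("NN", "everyone"))
  # vectorized
  expect_identical(mailing_eligible(c("", "RN", "NR"), "previous_year"),
                   c(TRUE, FALSE, TRUE))
})

test_that("return probabilities follow history keys, fallbacks and overrides", {
  b <- behavior_params()
  expect_identical(return_probability("", b), 0.19)
  expect_lt(return_probability("N", b), 0.03)
  expect_identical(return_probability("R", b),
                   default_conditional_return()[["yes_1"]])
  expect_identical(return_probability("RNR", b),
                   default_conditional_return()[["yes_2"]])

  # fallback: a key beyond the table reuses the largest tabulated prior count
  short <- behavior_params(conditional_return = c(yes_1 = 0.5, no_0 = 0.02,
                                                  no_1 = 0.1))
  expect_identical(return_probability("RRRR", short), 0.5)
  expect_identical(return_probability("RRN", short), 0.1)
  # no admissible fallback is a configuration error
  broken <- behavior_params(conditional_return = c(yes_2 = 0.5, no_0 = 0.02))
  expect_error(return_probability("R", broken), "yes_1")

  # full-history overrides take precedence over the keyed table
  over <- behavior_params(history_overrides = c(RN = 0.42))
  expect_identical(return_probability("RN", over), 0.42)
  expect_identical(return_probability("NRN", over),
                   default_conditional_return()[["no_1"]])
})

test_that("year-1 cascade reproduces the hand-multiplied volumes", {
  cfg <- model_config("everyone", "regional")  # 95% unspoiled, 70% navigation
  step <- advance_year(init_cohort_state(cfg), cfg)
  v <- step$volumes
  expect_equal(v$mailed, 215000)
  expect_equal(v$returned_kits, 40850)
  expect_equal(v$unspoiled_screens, 38807.5)
  expect_equal(v$positives, 2328.45)
  expect_equal(v$colonoscopies, 1629.915)
  expect_equal(v$crc_detected, 73.346175)
  expect_equal(v$reminders, 215000 * 0.83)
  # positive patients left the pool
  expect_equal(step$state$exited_positive, 2328.45)
})

test_that("the expected-value identity chain holds exactly in every year", {
  for (cfg in default_scenarios()[c("previous_year_centralized",
                                    "at_least_once_hybrid",
                                    "everyone_regional")]) {
    y <- run_scenario(cfg)$yearly
    expect_equal(y$unspoiled_screens, y$returned_kits * cfg$org$unspoiled_rate)
    expect_true(all(y$positives <= y$unspoiled_screens))
    expect_equal(y$colonoscopies, y$positives * cfg$org$navigation_success)
    expect_equal(y$crc_detected,
                 y$colonoscopies * cfg$behavior$crc_detection_rate)
    expect_equal(y$adenomas_detected,
                 y$colonoscopies * cfg$behavior$adenoma_detection_rate)
    expect_equal(y$reminders, y$mailed * cfg$behavior$reminder_fraction)
  }
})

test_that("patient counts are conserved year over year", {
  cfg <- model_config("everyone", "hybrid",
                      behavior = behavior_params(optout_rate = 0.05))
  state <- init_cohort_state(cfg)
  for (t in 1:5) {
    pool_before <- sum(state$strata$count)
    entrants <- if (t >= 2) new_entrants(cfg$cohort, t) else 0
    exits_before <- state$exited_positive + state$exited_optout
    step <- advance_year(state, cfg)
    state <- step$state
    pool_after <- sum(state$strata$count)
    exits_after <- state$exited_positive + state$exited_optout
    expect_equal(pool_after + (exits_after - exits_before),
                 pool_before + entrants)
    # history length always equals years since entry
    expect_true(all(nchar(state$strata$history) ==
                      state$year - state$strata$entry_year))
  }
})

test_that("degenerate cohorts propagate to zero volumes", {
  cfg <- tiny_config()
  cfg$cohort$initial_unscreened <- 0
  cfg$cohort$annual_growth <- 0
  v <- run_scenario(cfg)
  expect_true(all(v$totals == 0))

  # absorbing non-response: with zero conditional probabilities the
  # previous-year strategy only ever collects first-year returns of entrants
  cfg2 <- model_config("previous_year", "hybrid",
                       behavior = behavior_params(
                         conditional_return = c(yes_1 = 0, no_0 = 0)))
  y <- run_scenario(cfg2)$yearly
  expected <- c(215000 * 0.19,
                vapply(2:5, function(t)
                  new_entrants(cfg2$cohort, t) * 0.19, numeric(1)))
  expect_equal(y$returned_kits, expected)
})

test_that("a one-year horizon reduces totals to the first year", {
  cfg <- model_config("at_least_once", "hybrid",
                      cohort = cohort_params(horizon = 1))
  v <- run_scenario(cfg)
  expect_identical(nrow(v$yearly), 1L)
  expect_equal(unname(v$totals["mailed"]), 215000)
})

test_that("outreach strategies are ordered by reach, and spoilage by organization", {
  totals <- lapply(run_scenarios(), function(r) r$volumes$totals)
  for (o in c("centralized", "hybrid", "regional")) {
    ev <- totals[[paste0("everyone_", o)]]
    alo <- totals[[paste0("at_least_once_", o)]]
    py <- totals[[paste0("previous_year_", o)]]
    for (m in names(ev)) {
      expect_gte(ev[[m]], alo[[m]])
      expect_gte(alo[[m]], py[[m]])
    }
  }
  # centralized and hybrid share the spoilage rate, hence screen counts;
  # regional processes more screens per returned kit
  for (s in outreach_strategies()) {
    cen <- totals[[paste0(s, "_centralized")]]
    hyb <- totals[[paste0(s, "_hybrid")]]
    reg <- totals[[paste0(s, "_regional")]]
    expect_equal(cen[["unspoiled_screens"]], hyb[["unspoiled_screens"]])
    expect_gt(reg[["unspoiled_screens"]] / reg[["returned_kits"]],
              hyb[["unspoiled_screens"]] / hyb[["returned_kits"]])
  }
})
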