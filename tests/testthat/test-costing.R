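zero_volumes <- function(year = 2, ...) {
  v <- tibble::tibble(year = year, mailed = 0, reminders = 0,
                      returned_kits = 0, unspoiled_screens = 0, positives = 0,
                      navigations = 0, colonoscopies = 0, crc_detected = 0,
                      adenomas_detected = 0, postcards_returned = 0)
  mods <- list(...)
  for (nm in names(mods)) v[[nm]] <- mods[[nm]]
  v
}

test_that("direct cost prices each line item at its published unit cost", {
  u <- unit_costs()
  # a single mailer in year 2 incurs its unit cost plus the reply-mail fee
  d <- direct_cost(zero_volumes(mailed = 1), u, org_config("hybrid"), year = 2)
  expect_equal(sum(d), 6.73 + 275)
  # navigation line, centralized: wage x 18 min per positive
  d <- direct_cost(zero_volumes(positives = 100), u, org_config("centralized"),
                   year = 2)
  expect_equal(d[["navigation"]], 100 * 39.59 * 18 / 60)  # $1,188
  expect_equal(d[["positive_calls"]], 100 * 3.96)
  # zero volumes in year 2: the annual fixed fee is the only charge
  d <- direct_cost(zero_volumes(), u, org_config("hybrid"), year = 2)
  expect_equal(sum(d), 275)
  # year 1 additionally carries the one-time text set-up, per mailing site
  d1 <- direct_cost(zero_volumes(year = 1), u, org_config("regional"), year = 1)
  expect_equal(sum(d1), (78.95 + 275) * 7)
  # returned kits are billed the organizational fee, spoiled included
  d <- direct_cost(zero_volumes(returned_kits = 10, unspoiled_screens = 9),
                   u, org_config("regional"), year = 2)
  expect_equal(d[["fit_processing"]], 10 * 23)
  expect_equal(d[["results_letters"]], 9 * 1.15)
  expect_equal(d[["result_updates"]], 9 * 0.97)
})

test_that("payer colonoscopy cost covers the uninsured share only", {
  expect_equal(payer_colonoscopy_cost(1000, cohort_params(), unit_costs()),
               702000)
  expect_identical(
    payer_colonoscopy_cost(1000, cohort_params(uninsured_fraction = 0),
                           unit_costs()), 0)
  expect_equal(
    payer_colonoscopy_cost(1000, cohort_params(uninsured_fraction = 1),
                           unit_costs()), 1000 * 1800)
})

test_that("overheads follow the configuration rates on the non-colonoscopy base", {
  oh <- apply_overheads(c(1e6, 2e6), org_config("regional"))
  expect_equal(oh$indirect_by_year, c(240000, 480000))
  expect_equal(oh$startup, 0.10 * (1e6 + 240000))

  zero <- org_config("hybrid", indirect_rate = 0, startup_rate = 0)
  oh0 <- apply_overheads(c(1e6, 2e6), zero)
  expect_identical(oh0$indirect_by_year, c(0, 0))
  expect_identical(oh0$startup, 0)

  # centralized overheads strictly below regional on identical direct costs
  ohc <- apply_overheads(1e6, org_config("centralized"))
  ohr <- apply_overheads(1e6, org_config("regional"))
  expect_lt(ohc$indirect_by_year, ohr$indirect_by_year)
  expect_lt(ohc$startup, ohr$startup)
})

test_that("total cost is linear in unit costs and additive over years", {
  cfg <- tiny_config()
  cfg$org$indirect_rate <- 0
  cfg$org$startup_rate <- 0
  cfg$cohort$uninsured_fraction <- 0
  v <- run_scenario(cfg)
  base <- total_cost(cfg, v)

  doubled <- cfg
  for (nm in names(doubled$costs)) doubled$costs[[nm]] <- doubled$costs[[nm]] * 2
  doubled$org$fit_fee <- doubled$org$fit_fee * 2
  expect_equal(total_cost(doubled, v)$total, 2 * base$total)

  # undiscounted: total equals the simple sum of yearly flows plus start-up
  full <- model_config("at_least_once", "hybrid")
  cc <- total_cost(full, run_scenario(full))
  expect_equal(cc$total,
               cc$startup + sum(cc$yearly$direct_total + cc$yearly$indirect +
                                  cc$yearly$colonoscopy_payer))
  # a positive discount rate shrinks later flows
  disc <- model_config("at_least_once", "hybrid", discount_rate = 0.03)
  cc_d <- total_cost(disc, run_scenario(disc))
  expect_lt(cc_d$total, cc$total)
  expect_gt(cc_d$total, cc$total / 1.03^4)
})

test_that("cost ordering across scenarios matches program reach", {
  costs <- vapply(run_scenarios(), function(r) r$total_cost, numeric(1))
  for (o in c("centralized", "hybrid", "regional")) {
    expect_lt(costs[[paste0("previous_year_", o)]],
              costs[[paste0("at_least_once_", o)]])
    expect_lt(costs[[paste0("at_least_once_", o)]],
              costs[[paste0("everyone_", o)]])
  }
})
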