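test_that("pairwise ICERs handle the standard and degenerate cases", {
  expect_equal(icer(list(cost = 0, effect = 0),
                    list(cost = 10.6e6, effect = 194)),
               10.6e6 / 194)
  expect_equal(icer(list(cost = 10.6e6, effect = 194),
                    list(cost = 11.9e6, effect = 204)), 130000)
  # identical costs, more effect: free improvement, ICER 0
  expect_identical(icer(list(cost = 5, effect = 1), list(cost = 5, effect = 2)),
                   0)
  expect_error(icer(list(cost = 1, effect = 2), list(cost = 2, effect = 2)),
               "equal effects")
  expect_error(icer(list(cost = 1, effect = 3), list(cost = 2, effect = 2)),
               "less effective")
})

test_that("strict dominance and tie handling are deterministic", {
  fr <- dominance_frontier(tibble::tibble(label = c("a", "b"),
                                          cost = c(10, 8),
                                          effect = c(5, 6)))
  expect_identical(fr$status[fr$label == "a"], "strictly_dominated")
  expect_identical(fr$status[fr$label == "b"], "nondominated")

  # cost ties: higher effect first, lower effect strictly dominated
  fr <- dominance_frontier(tibble::tibble(label = c("lo", "hi"),
                                          cost = c(8, 8), effect = c(3, 6)))
  expect_identical(fr$label[1], "hi")
  expect_identical(fr$status, c("nondominated", "strictly_dominated"))

  expect_warning(
    fr <- dominance_frontier(tibble::tibble(label = c("x", "x2", "y"),
                                            cost = c(1, 1, 2),
                                            effect = c(1, 1, 3))),
    "duplicate")
  expect_identical(nrow(fr), 2L)
})

test_that("published scenario table yields the published frontier", {
  fr <- dominance_frontier(reference_options())
  nd <- fr$label[fr$status == "nondominated"]
  expect_setequal(nd, c("no_program", "at_least_once_hybrid",
                        "at_least_once_regional", "everyone_regional"))
  expect_identical(sum(fr$status == "weakly_dominated"), 6L)
  # frontier ICERs strictly increase with cost
  icers <- fr$icer[fr$status == "nondominated"]
  expect_true(all(diff(na.omit(icers)) > 0))
})

test_that("frontier equals the brute-force convex-combination oracle", {
  set.seed(7)
  for (i in 1:200) {
    opts <- random_options(sample(2:8, 1), include_anchor = i %% 2 == 0)
    fr <- dominance_frontier(opts)
    expect_identical(sort(fr$label[fr$status == "nondominated"]),
                     oracle_nondominated(opts))
  }
})

test_that("fixed-budget scaling is linear and anchored at the actual budget", {
  res <- evaluate_scenario(tiny_config())
  a <- acer_fixed_budget(res, budget = res$total_cost)
  expect_equal(a$scaled_outcomes, unclass(res$outcomes))

  a1 <- acer_fixed_budget(res, budget = 5e6)
  a2 <- acer_fixed_budget(res, budget = 10e6)
  expect_equal(a2$scaled_outcomes, 2 * a1$scaled_outcomes)
  # ACERs do not depend on the budget
  expect_equal(a1$acers, a2$acers)

  # zero outcomes have undefined ACERs
  res0 <- res
  res0$outcomes[["crc_prevented"]] <- 0
  a0 <- acer_fixed_budget(res0, 5e6)
  expect_true(is.na(a0$acers[["crc_prevented"]]))
})

test_that("the most efficient scenario is budget-invariant and strategy-consistent", {
  results <- run_scenarios()
  for (budget in c(2e6, 5e6, 20e6)) {
    tab <- acer_table(results, budget = budget)
    for (k in c("crc_detected", "crc_prevented", "crc_deaths_prevented")) {
      best <- tab$label[which.min(tab[[paste0("acer_", k)]])]
      expect_identical(best, "at_least_once_hybrid")
    }
  }
  # within every organization, the at-least-once strategy has the lowest ACER
  tab <- acer_table(results)
  for (o in c("centralized", "hybrid", "regional")) {
    sub <- tab[tab$org == o, ]
    expect_identical(sub$strategy[which.min(sub$acer_crc_detected)],
                     "at_least_once")
  }
})
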