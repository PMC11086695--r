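#' Cost-effectiveness analysis
#'
#' Two complementary views. The incremental view sorts scenarios by cost,
#' eliminates strictly dominated options (another option is cheaper and more
#' effective) and weakly (extended) dominated options (a linear combination
#' of two other options is cheaper and more effective), and reports the ICER
#' of each surviving option against the previous survivor. The average view
#' divides total cost by total outcome (ACER) and scales outcomes linearly
#' to a fixed budget, identifying the most efficient scenario under a budget
#' constraint.
#'
#' @name fitreach-cea
NULL

#' Incremental cost-effectiveness ratio between two options
#'
#' `(cost_b - cost_a) / (effect_b - effect_a)`, in dollars per outcome unit.
#' The comparator `a` must be the less effective option; equal effects make
#' the ratio undefined and raise an error.
#'
#' @param a,b Options: lists or one-row data frames with `cost` and `effect`.
#' @return Dollars per additional unit of outcome.
#' @examples
#' icer(list(cost = 0, effect = 0), list(cost = 10.6e6, effect = 194))
#' @export
icer <- function(a, b) {
  ca <- as.numeric(a$cost); ea <- as.numeric(a$effect)
  cb <- as.numeric(b$cost); eb <- as.numeric(b$effect)
  if (eb == ea) stop("ICER undefined: options have equal effects", call. = FALSE)
  if (eb < ea) stop("ICER comparator must be the less effective option",
                    call. = FALSE)
  (cb - ca) / (eb - ea)
}

#' Dominance frontier with ICERs
#'
#' Options are sorted by cost (ties broken by higher effect first; exact
#' duplicate (cost, effect) pairs are collapsed with a warning). Strictly
#' dominated options are marked first. Extended dominance is then resolved
#' by repeated sweeps: whenever the ICER of an option against the previous
#' survivor is at least the ICER of the next survivor against it, the option
#' is weakly dominated and removed; sweeps repeat until the surviving ICERs
#' are strictly increasing in cost, which is equivalent to keeping the lower
#' convex hull of the (effect, cost) cloud. Include a `(0, 0)` "no program"
#' anchor row to express dominance against doing nothing.
#'
#' @param options Data frame or tibble with columns `label`, `cost`,
#'   `effect`.
#' @return Tibble: input rows sorted by cost with `status` (`"nondominated"`,
#'   `"strictly_dominated"`, `"weakly_dominated"`) and `icer` (dollars per
#'   outcome unit versus the previous nondominated option; `NA` for
#'   dominated options and for the least costly survivor).
#' @examples
#' opts <- tibble::tibble(label = c("none", "a", "b"),
#'                        cost = c(0, 8, 10), effect = c(0, 6, 5))
#' dominance_frontier(opts)
#' @export
dominance_frontier <- function(options) {
  options <- tibble::as_tibble(options)
  stopifnot(nrow(options) >= 1,
            all(c("label", "cost", "effect") %in% names(options)))
  dup <- duplicated(options[, c("cost", "effect")])
  if (any(dup)) {
    warning(sprintf("collapsing %d duplicate (cost, effect) option(s): %s",
                    sum(dup), paste(options$label[dup], collapse = ", ")))
    options <- options[!dup, , drop = FALSE]
  }
  ord <- order(options$cost, -options$effect)
  options <- options[ord, , drop = FALSE]
  n <- nrow(options)

  status <- rep("nondominated", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (options$cost[j] <= options$cost[i] &&
          options$effect[j] >= options$effect[i] &&
          (options$cost[j] < options$cost[i] ||
           options$effect[j] > options$effect[i])) {
        status[i] <- "strictly_dominated"
        break
      }
    }
  }

  # extended dominance: repeated ICER-monotonicity sweeps until stable
  alive <- which(status == "nondominated")
  repeat {
    if (length(alive) < 3) break
    cost <- options$cost[alive]; eff <- options$effect[alive]
    ic <- diff(cost) / diff(eff)  # ICER of alive[i+1] vs alive[i]
    bad <- which(ic[-length(ic)] >= ic[-1])  # option alive[bad + 1] is WD
    if (length(bad) == 0) break
    status[alive[bad[1] + 1]] <- "weakly_dominated"
    alive <- alive[-(bad[1] + 1)]
  }

  icers <- rep(NA_real_, n)
  if (length(alive) >= 2) {
    icers[alive[-1]] <- diff(options$cost[alive]) / diff(options$effect[alive])
  }
  options$status <- status
  options$icer <- icers
  options
}

#' Budget-constrained average cost-effectiveness
#'
#' For each outcome, the ACER is the scenario's total cost divided by the
#' outcome total, and the outcome achievable within a fixed budget is
#' `budget / ACER` (linear scaling of the program, with no integer
#' constraints). The scenario minimizing an outcome's ACER maximizes that
#' outcome under any budget.
#'
#' @param result A `fitreach_result` from [evaluate_scenario()], or any list
#'   with a scalar `total_cost` and a named `outcomes` vector.
#' @param budget Fixed budget in dollars (default $5 million).
#' @return List with `acers` (dollars per outcome unit), `scaled_outcomes`
#'   (outcome achieved at the budget), `budget` and `total_cost`. Outcomes
#'   equal to zero give `NA` ACERs.
#' @examples
#' res <- evaluate_scenario(model_config("at_least_once", "hybrid"))
#' acer_fixed_budget(res, 5e6)$scaled_outcomes[["crc_detected"]]
#' @export
acer_fixed_budget <- function(result, budget = 5e6) {
  total_cost <- result$total_cost
  outcomes <- unclass(result$outcomes)
  stopifnot(is.numeric(total_cost), total_cost > 0, budget >= 0)
  acers <- ifelse(outcomes > 0, total_cost / outcomes, NA_real_)
  scaled <- budget / acers
  list(acers = acers, scaled_outcomes = scaled, budget = budget,
       total_cost = total_cost)
}
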