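# Shared fixtures and independent oracles for the test suite.

# Small, fast configuration for property-style loops.
tiny_config <- function(strategy = "at_least_once", org = "hybrid", ...) {
  model_config(strategy, org,
               cohort = cohort_params(initial_unscreened = 1000,
                                      annual_growth = 0.05, horizon = 3),
               ...)
}

# Brute-force dominance oracle, independent of dominance_frontier():
# option i is dominated iff some single option or some convex combination of
# two options is at least as cheap and at least as effective, strictly so in
# at least one dimension. For a pair, the cheapest combination with effect
# >= e_i sits at an endpoint of the feasible effect interval, cost being
# linear along the segment.
oracle_nondominated <- function(options) {
  n <- nrow(options)
  cost <- options$cost; eff <- options$effect
  dominated <- logical(n)
  dominates_point <- function(c2, e2, c1, e1) {
    c2 <= c1 && e2 >= e1 && (c2 < c1 || e2 > e1)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i && dominates_point(cost[j], eff[j], cost[i], eff[i])) {
        dominated[i] <- TRUE
      }
    }
    if (dominated[i]) next
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        if (j == i || k == i) next
        e_lo <- min(eff[j], eff[k]); e_hi <- max(eff[j], eff[k])
        if (e_hi < eff[i]) next
        interp_cost <- function(e) {
          if (eff[j] == eff[k]) return(min(cost[j], cost[k]))
          lam <- (e - eff[k]) / (eff[j] - eff[k])
          lam * cost[j] + (1 - lam) * cost[k]
        }
        for (e_star in c(max(eff[i], e_lo), e_hi)) {
          if (dominates_point(interp_cost(e_star), e_star, cost[i], eff[i])) {
            dominated[i] <- TRUE
          }
        }
        if (dominated[i]) break
      }
      if (dominated[i]) break
    }
  }
  sort(options$label[!dominated])
}

random_options <- function(n, include_anchor = TRUE) {
  opts <- tibble::tibble(label = paste0("opt", seq_len(n)),
                         cost = stats::runif(n, 0, 100),
                         effect = stats::runif(n, 0, 10))
  if (include_anchor) {
    opts <- rbind(tibble::tibble(label = "anchor", cost = 0, effect = 0), opts)
  }
  opts
}

# Reference options for the worked CEA example: published 5-year cost and
# CRC-detected columns plus the no-program anchor.
reference_options <- function() {
  ref <- reference_estimates()
  rbind(tibble::tibble(label = "no_program", cost = 0, effect = 0),
        tibble::tibble(label = paste(ref$strategy, ref$org, sep = "_"),
                       cost = ref$cost_millions * 1e6,
                       effect = ref$crc_detected))
}
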