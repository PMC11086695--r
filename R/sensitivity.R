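#' Sensitivity analysis
#'
#' One-way analysis re-runs the full pipeline over a grid for a shared
#' parameter (at least +/-20% around its base value) and reports whether the
#' scenario rank ordering by ICER and ACER changes. Threshold analysis
#' bisects a configuration-specific parameter of one scenario until its ACER
#' equals that of a comparator scenario.
#'
#' @name fitreach-sensitivity
NULL

#' Registered sensitivity parameters
#'
#' Shared parameters: `annual_growth`, `first_return_rate`, `positivity`
#' (scales the initial and later positivity rates together),
#' `crc_detection_rate`, `direct_cost` (a multiplier on every direct unit
#' cost including the laboratory FIT fee), `uninsured_fraction`,
#' `discount_rate`. Organizational parameters (used in threshold analysis):
#' `indirect_rate`, `startup_rate`, `unspoiled_rate`, `navigation_success`,
#' `fit_fee`, `navigation_minutes`.
#'
#' @return Character vector of registered parameter names.
#' @export
sensitivity_parameters <- function() names(.param_registry())

.clip01 <- function(x) pmin(pmax(x, 0), 1)

.param_registry <- function() {
  frac <- function(get, set) list(get = get, set = set, lower = 0, upper = 1)
  pos <- function(get, set) list(get = get, set = set, lower = 0, upper = Inf)
  list(
    annual_growth = frac(
      function(cfg) cfg$cohort$annual_growth,
      function(cfg, v) { cfg$cohort$annual_growth <- .clip01(v); cfg }),
    first_return_rate = frac(
      function(cfg) cfg$behavior$first_return_rate,
      function(cfg, v) { cfg$behavior$first_return_rate <- .clip01(v); cfg }),
    positivity = frac(
      function(cfg) cfg$behavior$positivity_initial,
      function(cfg, v) {
        ratio <- .clip01(v) / cfg$behavior$positivity_initial
        cfg$behavior$positivity_initial <- .clip01(v)
        cfg$behavior$positivity_later <- .clip01(cfg$behavior$positivity_later * ratio)
        cfg
      }),
    crc_detection_rate = frac(
      function(cfg) cfg$behavior$crc_detection_rate,
      function(cfg, v) { cfg$behavior$crc_detection_rate <- .clip01(v); cfg }),
    direct_cost = pos(
      function(cfg) 1,
      function(cfg, v) {
        stopifnot(v >= 0)
        for (nm in setdiff(names(cfg$costs), character())) {
          cfg$costs[[nm]] <- cfg$costs[[nm]] * v
        }
        cfg$org$fit_fee <- cfg$org$fit_fee * v
        cfg
      }),
    uninsured_fraction = frac(
      function(cfg) cfg$cohort$uninsured_fraction,
      function(cfg, v) { cfg$cohort$uninsured_fraction <- .clip01(v); cfg }),
    discount_rate = frac(
      function(cfg) cfg$discount_rate,
      function(cfg, v) { cfg$discount_rate <- .clip01(v); cfg }),
    indirect_rate = frac(
      function(cfg) cfg$org$indirect_rate,
      function(cfg, v) { cfg$org$indirect_rate <- .clip01(v); cfg }),
    startup_rate = frac(
      function(cfg) cfg$org$startup_rate,
      function(cfg, v) { cfg$org$startup_rate <- .clip01(v); cfg }),
    unspoiled_rate = frac(
      function(cfg) cfg$org$unspoiled_rate,
      function(cfg, v) { cfg$org$unspoiled_rate <- .clip01(v); cfg }),
    navigation_success = frac(
      function(cfg) cfg$org$navigation_success,
      function(cfg, v) { cfg$org$navigation_success <- .clip01(v); cfg }),
    fit_fee = pos(
      function(cfg) cfg$org$fit_fee,
      function(cfg, v) { stopifnot(v >= 0); cfg$org$fit_fee <- v; cfg }),
    navigation_minutes = pos(
      function(cfg) cfg$org$navigation_minutes,
      function(cfg, v) { stopifnot(v >= 0); cfg$org$navigation_minutes <- v; cfg })
  )
}

.get_param <- function(name) {
  reg <- .param_registry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown sensitivity parameter \"%s\"; see sensitivity_parameters()",
                 name), call. = FALSE)
  }
  reg[[name]]
}

.frontier_sequence <- function(summary, outcome) {
  fr <- dominance_frontier(tibble::tibble(label = summary$label,
                                          cost = summary$cost,
                                          effect = summary[[outcome]]))
  fr$label[fr$status == "nondominated"]
}

.acer_ranking <- function(summary, outcome) {
  s <- summary[summary$label != "no_program", , drop = FALSE]
  s$label[order(s$cost / s[[outcome]])]
}

#' One-way sensitivity analysis
#'
#' Re-runs every scenario at each grid point of one shared parameter and
#' reports total cost, the chosen outcome, ACERs, frontier membership and
#' ICERs, plus whether the scenario rank ordering (by ACER, and the ordered
#' nondominated frontier) differs anywhere on the grid from the base run.
#'
#' @param parameter A name from [sensitivity_parameters()].
#' @param relative_range Half-width of the grid relative to the base value
#'   (default 0.2, i.e. +/-20%).
#' @param n_points Number of grid points (default 5).
#' @param configs Named list of configurations (default the nine scenarios).
#' @param outcome Outcome column used for ICER/ACER rank ordering.
#' @param grid Optional explicit grid of parameter values, overriding
#'   `relative_range`/`n_points`. The discount rate, whose base value is 0,
#'   defaults to a 0 to 3%/year grid.
#' @return A `fitreach_one_way`: list with `parameter`, `grid`, `metrics`
#'   (tibble: value x scenario with cost, outcome, ACER, status, ICER) and
#'   `rank_order_changed`.
#' @export
one_way <- function(parameter, relative_range = 0.2, n_points = 5,
                    configs = default_scenarios(), outcome = "crc_detected",
                    grid = NULL) {
  p <- .get_param(parameter)
  stopifnot(relative_range >= 0, n_points >= 1, length(configs) >= 1)
  base_value <- p$get(configs[[1]])
  if (is.null(grid)) {
    if (parameter == "discount_rate" && base_value == 0) {
      grid <- seq(0, 0.03, length.out = n_points)
    } else if (relative_range == 0) {
      grid <- base_value
    } else {
      grid <- seq(base_value * (1 - relative_range),
                  base_value * (1 + relative_range), length.out = n_points)
      grid <- pmin(pmax(grid, p$lower), p$upper)
    }
  }
  eval_point <- function(v) {
    res <- run_scenarios(lapply(configs, p$set, v = v))
    s <- scenario_summary(res, include_no_program = TRUE)
    ct <- cea_table(s, outcomes = outcome)
    ct$value <- v
    ct$acer <- ifelse(ct$label == "no_program", NA_real_,
                      ct$cost / ct[[outcome]])
    ct
  }
  pts <- lapply(grid, eval_point)
  base_point <- if (base_value %in% grid) {
    pts[[match(base_value, grid)]]
  } else eval_point(base_value)
  base_rank <- .acer_ranking(base_point, outcome)
  base_frontier <- .frontier_sequence(base_point, outcome)
  changed <- any(vapply(pts, function(ct) {
    !identical(.acer_ranking(ct, outcome), base_rank) ||
      !identical(.frontier_sequence(ct, outcome), base_frontier)
  }, logical(1)))
  metrics <- do.call(rbind, pts)
  structure(list(parameter = parameter, grid = grid, outcome = outcome,
                 metrics = metrics, base_value = base_value,
                 rank_order_changed = changed),
            class = "fitreach_one_way")
}

#' @export
print.fitreach_one_way <- function(x, ...) {
  cat("<fitreach_one_way> ", x$parameter, ": grid [",
      paste(signif(range(x$grid), 4), collapse = ", "), "], ",
      length(x$grid), " points\n", sep = "")
  cat("  rank order (ICER frontier and ACER, by ", x$outcome, ") changed: ",
      x$rank_order_changed, "\n", sep = "")
  invisible(x)
}

#' Threshold sensitivity analysis between two configurations
#'
#' Varies one parameter of scenario A until its ACER for the chosen outcome
#' equals scenario B's base ACER, by root bisection on the ACER gap. The
#' default bracket is 0.5x to 1.5x the parameter's base value, clipped to
#' its admissible range; if the gap does not change sign over the bracket,
#' the result reports no threshold in range.
#'
#' @param config_a Configuration whose parameter is varied.
#' @param config_b Fixed comparator configuration.
#' @param parameter Name from [sensitivity_parameters()].
#' @param outcome Outcome for the ACER comparison (default CRC detected).
#' @param tolerance Relative ACER gap accepted at the threshold
#'   (default 1e-6).
#' @param bracket Optional length-2 numeric search bracket.
#' @return A `fitreach_threshold`: list with `parameter`, `outcome`,
#'   `threshold` (`NA` if no sign change), `achieved_gap` (relative),
#'   `acer_a`, `acer_b`, `base_value` and `bracket`.
#' @examples
#' th <- threshold_search(model_config("at_least_once", "centralized"),
#'                        model_config("at_least_once", "hybrid"),
#'                        "navigation_success")
#' th$threshold
#' @export
threshold_search <- function(config_a, config_b, parameter,
                             outcome = "crc_detected", tolerance = 1e-6,
                             bracket = NULL) {
  p <- .get_param(parameter)
  base_value <- p$get(config_a)
  res_b <- evaluate_scenario(config_b)
  acer_b <- res_b$total_cost / res_b$outcomes[[outcome]]
  acer_a_at <- function(v) {
    res <- evaluate_scenario(p$set(config_a, v))
    res$total_cost / res$outcomes[[outcome]]
  }
  gap <- function(v) acer_a_at(v) - acer_b
  if (is.null(bracket)) {
    bracket <- c(max(0.5 * base_value, p$lower),
                 min(1.5 * base_value, p$upper))
  }
  g_lo <- gap(bracket[1]); g_hi <- gap(bracket[2])
  out <- list(parameter = parameter, outcome = outcome,
              base_value = base_value, bracket = bracket, acer_b = acer_b)
  if (is.na(g_lo) || is.na(g_hi) || g_lo * g_hi > 0) {
    out$threshold <- NA_real_
    out$achieved_gap <- NA_real_
    out$acer_a <- acer_a_at(base_value)
    out$message <- "no threshold in range"
    return(structure(out, class = "fitreach_threshold"))
  }
  root <- stats::uniroot(gap, interval = bracket, tol = .Machine$double.eps^0.5)
  out$threshold <- root$root
  out$acer_a <- acer_a_at(root$root)
  out$achieved_gap <- (out$acer_a - acer_b) / acer_b
  if (abs(out$achieved_gap) > tolerance) {
    # polish with tighter bisection if uniroot's x-tolerance was not enough
    lo <- max(bracket[1], root$root - 1e-6); hi <- min(bracket[2], root$root + 1e-6)
    if (gap(lo) * gap(hi) <= 0) {
      root <- stats::uniroot(gap, c(lo, hi), tol = .Machine$double.eps)
      out$threshold <- root$root
      out$acer_a <- acer_a_at(root$root)
      out$achieved_gap <- (out$acer_a - acer_b) / acer_b
    }
  }
  out$message <- "converged"
  structure(out, class = "fitreach_threshold")
}

#' @export
print.fitreach_threshold <- function(x, ...) {
  cat("<fitreach_threshold> ", x$parameter, " (", x$outcome, ")\n", sep = "")
  if (is.na(x$threshold)) {
    cat("  ", x$message, " (bracket ",
        paste(signif(x$bracket, 4), collapse = " .. "), ")\n", sep = "")
  } else {
    cat(sprintf("  base %.4g -> threshold %.6g (relative ACER gap %.2e)\n",
                x$base_value, x$threshold, x$achieved_gap))
  }
  invisible(x)
}
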