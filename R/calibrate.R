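#' Reconstruct history-conditional return probabilities
#'
#' The engine needs return probabilities for every reachable participation
#' history, but only the first-year rate (19%) and an upper bound for year-1
#' non-responders (< 3%) are published directly; the full
#' history-conditional table is not. This routine reconstructs it by
#' calibration: four free probabilities - repeat return after a first
#' return (`yes_1`), repeat return for established returners (`yes_2+`),
#' return after never having returned (`no_0`, bounded above by the
#' published 3%), and return of lapsed returners (`no_1+`) - are fitted by
#' least squares on relative errors so the deterministic engine reproduces
#' the published nine-scenario 5-year totals of cost, processed screens and
#' colonoscopies ([reference_estimates()]).
#'
#' The fit is run once and its result is frozen in
#' [default_conditional_return()]; the routine is exported so the
#' calibration is reproducible and can be re-run against different targets.
#'
#' @param targets Tibble in the format of [reference_estimates()].
#' @param base_config Template configuration supplying all non-fitted
#'   parameters (default [model_config()] defaults).
#' @param start Numeric length-4 starting values
#'   `(yes_1, yes_2plus, no_0, no_1plus)`.
#' @param no0_max Upper bound for the never-returned probability
#'   (default 0.03, the published bound).
#' @param columns Target columns to fit, any of `"cost"`, `"screens"`,
#'   `"colonoscopies"`.
#' @param maxit Maximum Nelder-Mead iterations.
#' @param monotone Constrain the fit to behaviorally plausible orderings
#'   (`yes_2plus >= yes_1 >= no_1plus`, default `TRUE`): screening habit
#'   strengthens with repeated participation and lapsed returners respond
#'   less than recent returners. Without the constraint the totals can be
#'   matched marginally better by oscillating probabilities with no
#'   behavioral interpretation.
#' @return List with `probabilities` (named vector in
#'   [behavior_params()] `conditional_return` format), `objective` (sum of
#'   squared relative errors), `fit` (the raw [stats::optim()] result) and
#'   `comparison` (tibble of model vs target values).
#' @export
calibrate_return_probabilities <- function(targets = reference_estimates(),
                                           base_config = model_config(),
                                           start = c(0.5, 0.55, 0.025, 0.1),
                                           no0_max = 0.03,
                                           columns = c("cost", "screens",
                                                       "colonoscopies"),
                                           maxit = 400, monotone = TRUE) {
  columns <- match.arg(columns, several.ok = TRUE)
  stopifnot(length(start) == 4, all(start > 0), start[3] < no0_max,
            all(start[-3] < 1))
  if (monotone && !(start[2] >= start[1] && start[1] >= start[4])) {
    stop("`start` must satisfy yes_2plus >= yes_1 >= no_1plus when monotone",
         call. = FALSE)
  }
  horizon <- base_config$cohort$horizon

  theta_to_table <- function(theta) {
    ks <- seq_len(max(horizon - 1L, 1L))
    yes <- stats::setNames(ifelse(ks == 1, theta[1], theta[2]),
                           paste0("yes_", ks))
    no <- stats::setNames(c(theta[3], rep(theta[4], length(ks))),
                          paste0("no_", c(0L, ks)))
    c(yes, no)
  }

  model_values <- function(tab) {
    out <- vector("list", nrow(targets))
    for (i in seq_len(nrow(targets))) {
      cfg <- base_config
      cfg$strategy <- targets$strategy[i]
      cfg$org <- org_config(targets$org[i])
      cfg$behavior$conditional_return <- tab
      cfg$label <- paste(cfg$strategy, cfg$org$name, sep = "_")
      v <- run_scenario(cfg)
      cc <- total_cost(cfg, v)
      out[[i]] <- c(cost = cc$total / 1e6,
                    screens = v$totals[["unspoiled_screens"]] / 1e3,
                    colonoscopies = v$totals[["colonoscopies"]] / 1e3)
    }
    do.call(rbind, out)
  }

  target_mat <- cbind(cost = targets$cost_millions,
                      screens = targets$screens_thousands,
                      colonoscopies = targets$colonoscopies_thousands)

  # unconstrained parameterization: logits, with no_0 scaled into (0, no0_max)
  # and (if monotone) yes_1 / no_1plus expressed as fractions of the level above
  to_theta <- function(x) {
    p <- stats::plogis(x)
    if (monotone) {
      yes2 <- p[2]; yes1 <- yes2 * p[1]; no1 <- yes1 * p[4]
      c(yes1, yes2, p[3] * no0_max, no1)
    } else {
      c(p[1], p[2], p[3] * no0_max, p[4])
    }
  }
  from_theta <- function(theta) {
    if (monotone) {
      stats::qlogis(c(theta[1] / theta[2], theta[2], theta[3] / no0_max,
                      theta[4] / theta[1]))
    } else {
      stats::qlogis(c(theta[1], theta[2], theta[3] / no0_max, theta[4]))
    }
  }
  objective <- function(x) {
    m <- model_values(theta_to_table(to_theta(x)))
    sum(((m[, columns, drop = FALSE] - target_mat[, columns, drop = FALSE]) /
           target_mat[, columns, drop = FALSE])^2)
  }
  fit <- stats::optim(from_theta(start), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  theta <- to_theta(fit$par)
  tab <- theta_to_table(theta)
  m <- model_values(tab)
  comparison <- tibble::tibble(
    strategy = rep(targets$strategy, times = ncol(m)),
    org = rep(targets$org, times = ncol(m)),
    column = rep(colnames(m), each = nrow(m)),
    model = as.vector(m), target = as.vector(target_mat))
  list(probabilities = tab, objective = fit$value, fit = fit,
       comparison = comparison)
}
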