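#' Deterministic cohort engine
#'
#' The eligible population is propagated through the program horizon with
#' difference equations. Patients are tracked in strata defined by entry year
#' and exact participation history (a string of `R`/`N` for
#' returned / did-not-return, one letter per year since entry), with
#' expected-value (real, not integer) counts. Transition probabilities are
#' history-conditional, so the process is not time-homogeneous. Patients with
#' a positive result exit the mailing pool permanently (they enter
#' colonoscopy surveillance, which is not modeled), as do opt-outs.
#'
#' @name fitreach-engine
NULL

#' New entrants into the eligible cohort
#'
#' The cohort grows by `annual_growth` per year. Under the default
#' compounding rule, entrants in year t number
#' `initial_unscreened * g * (1 + g)^(t - 2)`, i.e. the eligible population
#' (initial cohort plus prior entrants) grows geometrically; with
#' `growth_compounding = FALSE` a constant `initial_unscreened * g` enter
#' each year. Year 1 has no entrants: the whole initial cohort is mailed.
#'
#' @param cohort A [cohort_params()].
#' @param year Program year, >= 2.
#' @return Expected number of newly eligible unscreened patients.
#' @examples
#' new_entrants(cohort_params(), 2)  # 10750
#' @export
new_entrants <- function(cohort, year) {
  stopifnot(inherits(cohort, "fitreach_cohort_params"), year >= 2)
  g <- cohort$annual_growth
  if (cohort$growth_compounding) {
    cohort$initial_unscreened * g * (1 + g)^(year - 2)
  } else {
    cohort$initial_unscreened * g
  }
}

#' Mailing eligibility of a history stratum
#'
#' Newly entered patients (empty history) are always mailed. Afterwards:
#' `"everyone"` mails every stratum still in the pool, `"at_least_once"`
#' mails strata with at least one prior return, `"previous_year"` mails
#' strata whose last outcome was a return. Opt-outs and patients with a
#' positive result are removed from the pool before this rule applies.
#'
#' @param history History string of `R`/`N` (may be `""` for new entrants).
#' @param strategy One of [outreach_strategies()].
#' @return Logical vector, `TRUE` where the stratum is mailed.
#' @export
mailing_eligible <- function(history, strategy) {
  strategy <- match.arg(tolower(strategy), outreach_strategies())
  empty <- !nzchar(history)
  switch(strategy,
    everyone = rep(TRUE, length(history)),
    at_least_once = empty | grepl("R", history, fixed = TRUE),
    previous_year = empty | substring(history, nchar(history)) == "R"
  )
}

.history_key <- function(history) {
  n_prior <- nchar(gsub("N", "", history, fixed = TRUE))
  last <- ifelse(substring(history, nchar(history)) == "R", "yes", "no")
  list(last = last, n_prior = n_prior, key = paste0(last, "_", n_prior))
}

#' History-conditional return probability
#'
#' Patients receiving their first mailing return with `first_return_rate`.
#' Otherwise the probability is looked up in `behavior$conditional_return`
#' by the `(returned last year, number of prior returns)` key, after first
#' checking `behavior$history_overrides` for an exact full-history match.
#' A missing key falls back to the entry with the same last-year flag and
#' the largest tabulated prior-return count not exceeding the requested one;
#' if none exists the configuration is rejected.
#'
#' @param history History string(s) of `R`/`N`.
#' @param behavior A [behavior_params()].
#' @return Numeric vector of return probabilities.
#' @examples
#' return_probability("", behavior_params())     # 0.19
#' return_probability("N", behavior_params())    # < 0.03
#' @export
return_probability <- function(history, behavior) {
  stopifnot(inherits(behavior, "fitreach_behavior_params"))
  p <- numeric(length(history))
  empty <- !nzchar(history)
  p[empty] <- behavior$first_return_rate
  if (any(!empty)) {
    h <- history[!empty]
    k <- .history_key(h)
    tab <- behavior$conditional_return
    pr <- vapply(seq_along(h), function(i) {
      key <- k$key[i]
      if (key %in% names(tab)) return(tab[[key]])
      # fall back to the largest tabulated prior count <= requested
      pat <- paste0("^", k$last[i], "_([0-9]+)$")
      cand <- names(tab)[grepl(pat, names(tab))]
      ks <- as.integer(sub(pat, "\\1", cand))
      ok <- ks <= k$n_prior[i]
      if (!any(ok)) {
        stop(sprintf(paste0("no conditional return probability for key \"%s\" ",
                            "and no fallback with a smaller prior count"),
                     key), call. = FALSE)
      }
      tab[[cand[ok][which.max(ks[ok])]]]
    }, numeric(1))
    if (!is.null(behavior$history_overrides)) {
      m <- match(h, names(behavior$history_overrides))
      pr[!is.na(m)] <- behavior$history_overrides[m[!is.na(m)]]
    }
    p[!empty] <- pr
  }
  p
}

.positivity <- function(history, year, behavior) {
  if (behavior$positivity_mode == "by_program_year") {
    rep(if (year == 1) behavior$positivity_initial else behavior$positivity_later,
        length(history))
  } else {
    first_screen <- !grepl("R", history, fixed = TRUE)
    ifelse(first_screen, behavior$positivity_initial, behavior$positivity_later)
  }
}

#' Initial cohort state
#'
#' @param config A [model_config()].
#' @return A `cohort_state`: the full initial cohort in a single empty-history
#'   stratum at year 1, with zero cumulative exits.
#' @export
init_cohort_state <- function(config) {
  structure(list(
    year = 1L,
    strata = data.frame(entry_year = 1L, history = "",
                        count = config$cohort$initial_unscreened,
                        stringsAsFactors = FALSE),
    exited_positive = 0,
    exited_optout = 0
  ), class = "fitreach_cohort_state")
}

#' @export
print.fitreach_cohort_state <- function(x, ...) {
  cat("<cohort_state> year ", x$year, ": ", nrow(x$strata), " strata, ",
      format(round(sum(x$strata$count)), big.mark = ","), " in pool, ",
      format(round(x$exited_positive), big.mark = ","), " exited positive, ",
      format(round(x$exited_optout), big.mark = ","), " opted out\n", sep = "")
  invisible(x)
}

#' Advance the cohort by one program year
#'
#' Computes the mailing pool for the current year (adding new entrants in
#' years 2+), splits each mailed stratum by its history-conditional return
#' probability, and applies the downstream cascade: spoilage, positivity,
#' navigation, and detection, all as expected values. Patients with a
#' positive result are removed from future mailing pools; opt-outs are drawn
#' from mailed non-returners. Histories are extended by one letter for every
#' stratum (unmailed strata record `N`).
#'
#' @param state A `cohort_state` (see [init_cohort_state()]).
#' @param config A [model_config()].
#' @return List with elements `state` (advanced to the next year) and
#'   `volumes` (one-row tibble of the year's process volumes).
#' @export
advance_year <- function(state, config) {
  stopifnot(inherits(state, "fitreach_cohort_state"),
            inherits(config, "fitreach_config"))
  b <- config$behavior
  org <- config$org
  year <- state$year
  strata <- state$strata

  if (year >= 2) {
    strata <- rbind(strata,
                    data.frame(entry_year = year, history = "",
                               count = new_entrants(config$cohort, year),
                               stringsAsFactors = FALSE))
  }

  eligible <- mailing_eligible(strata$history, config$strategy)
  p_ret <- return_probability(strata$history, b)
  pos_rate <- .positivity(strata$history, year, b)

  mailed_n <- strata$count * eligible
  returned <- mailed_n * p_ret
  unspoiled <- returned * org$unspoiled_rate
  positives <- unspoiled * pos_rate
  non_returned <- mailed_n - returned
  optouts <- non_returned * b$optout_rate

  volumes <- tibble::tibble(
    year = year,
    mailed = sum(mailed_n),
    reminders = sum(mailed_n) * b$reminder_fraction,
    returned_kits = sum(returned),
    unspoiled_screens = sum(unspoiled),
    positives = sum(positives),
    navigations = sum(positives),
    colonoscopies = sum(positives) * org$navigation_success,
    crc_detected = sum(positives) * org$navigation_success * b$crc_detection_rate,
    adenomas_detected = sum(positives) * org$navigation_success * b$adenoma_detection_rate,
    postcards_returned = sum(mailed_n) * b$postcard_return_rate
  )

  # children: returners (minus positive exits) and non-returners (minus opt-outs)
  ret_child <- data.frame(entry_year = strata$entry_year,
                          history = paste0(strata$history, "R"),
                          count = returned - positives,
                          stringsAsFactors = FALSE)
  non_child <- data.frame(entry_year = strata$entry_year,
                          history = paste0(strata$history, "N"),
                          count = ifelse(eligible, non_returned - optouts,
                                         strata$count),
                          stringsAsFactors = FALSE)
  new_strata <- rbind(ret_child[ret_child$count > 0, , drop = FALSE],
                      non_child[non_child$count > 0, , drop = FALSE])

  new_state <- structure(list(
    year = year + 1L,
    strata = new_strata,
    exited_positive = state$exited_positive + sum(positives),
    exited_optout = state$exited_optout + sum(optouts)
  ), class = "fitreach_cohort_state")

  list(state = new_state, volumes = volumes)
}

#' Run one scenario through the full horizon
#'
#' Iterates [advance_year()] from year 1 to the horizon and collects yearly
#' process volumes and their 5-year (horizon) totals.
#'
#' @param config A [model_config()].
#' @return A `fitreach_volumes` object: list with `yearly` (tibble, one row
#'   per year) and `totals` (named numeric vector summed over years).
#' @examples
#' v <- run_scenario(model_config("at_least_once", "hybrid"))
#' v$totals[["unspoiled_screens"]]
#' @export
run_scenario <- function(config) {
  state <- init_cohort_state(config)
  rows <- vector("list", config$cohort$horizon)
  for (t in seq_len(config$cohort$horizon)) {
    step <- advance_year(state, config)
    state <- step$state
    rows[[t]] <- step$volumes
  }
  yearly <- do.call(rbind, rows)
  totals <- colSums(yearly[, setdiff(names(yearly), "year")])
  structure(list(label = config$label, yearly = yearly, totals = totals,
                 final_state = state),
            class = "fitreach_volumes")
}

#' @export
print.fitreach_volumes <- function(x, ...) {
  cat("<fitreach_volumes> ", x$label, " (", nrow(x$yearly), " years)\n", sep = "")
  cat(sprintf("  mailed %.0f | screens %.0f | colonoscopies %.1f | CRC detected %.1f\n",
              x$totals[["mailed"]], x$totals[["unspoiled_screens"]],
              x$totals[["colonoscopies"]], x$totals[["crc_detected"]]))
  invisible(x)
}
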