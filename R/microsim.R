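#' Patient-level stochastic microsimulation
#'
#' A Bernoulli twin of the deterministic engine: each patient's yearly
#' return, spoilage, positivity, navigation and detection outcomes are
#' individual draws with exactly the probabilities the difference equations
#' use as expected values. It generates synthetic patient rosters with the
#' behavioral structure the deterministic model assumes, and serves as a
#' Monte Carlo oracle: aggregated volumes converge on the deterministic
#' values as the roster grows.
#'
#' @name fitreach-microsim
NULL

#' Simulate a synthetic patient roster
#'
#' The roster starts with `n_patients` in year 1; yearly entrants are scaled
#' down from the configured cohort in proportion `n_patients /
#' initial_unscreened` (rounded to whole patients). Opt-out and a positive
#' result remove a patient from all future mailings (absorbing exits). The
#' random stream is fixed by `seed` with a deterministic draw order, so the
#' same seed always reproduces the same roster.
#'
#' @param config A [model_config()].
#' @param n_patients Number of year-1 patients (>= 1).
#' @param seed Integer seed fixing the random stream.
#' @param keep_roster Keep per-patient-year records (default `TRUE`); set to
#'   `FALSE` to return aggregated volumes only.
#' @return A `fitreach_sim`: list with `roster` (tibble, one row per active
#'   patient-year: `patient_id`, `entry_year`, `year`, `mailed`, `returned`,
#'   `positive`, `navigated`, `crc_detected`, `opted_out`; `NULL` when
#'   `keep_roster = FALSE`), `yearly` volumes, `totals`, `n_patients`,
#'   `seed`.
#' @examples
#' sim <- simulate_roster(model_config("at_least_once", "hybrid"),
#'                        n_patients = 500, seed = 1)
#' sim$totals[["returned_kits"]]
#' @export
simulate_roster <- function(config, n_patients, seed, keep_roster = TRUE) {
  stopifnot(inherits(config, "fitreach_config"), n_patients >= 1)
  set.seed(seed)
  b <- config$behavior
  org <- config$org
  horizon <- config$cohort$horizon
  scale <- n_patients / config$cohort$initial_unscreened

  entry_year <- rep(1L, n_patients)
  active <- rep(TRUE, n_patients)
  last_returned <- rep(FALSE, n_patients)
  n_returns <- rep(0L, n_patients)
  history <- rep("", n_patients)

  vol_rows <- vector("list", horizon)
  roster_rows <- if (keep_roster) vector("list", horizon) else NULL

  for (t in seq_len(horizon)) {
    if (t >= 2) {
      k <- as.integer(round(new_entrants(config$cohort, t) * scale))
      if (k > 0) {
        entry_year <- c(entry_year, rep(t, k))
        active <- c(active, rep(TRUE, k))
        last_returned <- c(last_returned, rep(FALSE, k))
        n_returns <- c(n_returns, rep(0L, k))
        history <- c(history, rep("", k))
      }
    }
    n <- length(active)
    alive <- active & entry_year <= t
    newly <- entry_year == t
    mailed <- alive & (newly | switch(config$strategy,
      everyone = TRUE,
      at_least_once = n_returns > 0L,
      previous_year = last_returned))

    p_ret <- rep(0, n)
    if (any(mailed)) {
      p_ret[mailed] <- return_probability(history[mailed], b)
    }
    returned <- mailed & (stats::runif(n) < p_ret)
    reminded <- mailed & (stats::runif(n) < b$reminder_fraction)
    unspoiled <- returned & (stats::runif(n) < org$unspoiled_rate)
    pos_rate <- if (b$positivity_mode == "by_program_year") {
      rep(if (t == 1) b$positivity_initial else b$positivity_later, n)
    } else {
      ifelse(n_returns == 0L, b$positivity_initial, b$positivity_later)
    }
    positive <- unspoiled & (stats::runif(n) < pos_rate)
    navigated <- positive & (stats::runif(n) < org$navigation_success)
    crc <- navigated & (stats::runif(n) < b$crc_detection_rate)
    adenoma <- navigated & (stats::runif(n) < b$adenoma_detection_rate)
    optout <- mailed & !returned & (stats::runif(n) < b$optout_rate)
    postcard <- mailed & (stats::runif(n) < b$postcard_return_rate)

    vol_rows[[t]] <- tibble::tibble(
      year = t, mailed = sum(mailed), reminders = sum(reminded),
      returned_kits = sum(returned), unspoiled_screens = sum(unspoiled),
      positives = sum(positive), navigations = sum(positive),
      colonoscopies = sum(navigated), crc_detected = sum(crc),
      adenomas_detected = sum(adenoma), postcards_returned = sum(postcard))

    if (keep_roster && any(alive)) {
      roster_rows[[t]] <- tibble::tibble(
        patient_id = which(alive), entry_year = entry_year[alive], year = t,
        mailed = mailed[alive], returned = returned[alive],
        positive = positive[alive], navigated = navigated[alive],
        crc_detected = crc[alive], opted_out = optout[alive])
    }

    history[alive] <- paste0(history[alive],
                             ifelse(returned[alive], "R", "N"))
    n_returns <- n_returns + as.integer(returned)
    last_returned[alive] <- returned[alive]
    active[positive | optout] <- FALSE
  }

  yearly <- do.call(rbind, vol_rows)
  totals <- colSums(yearly[, setdiff(names(yearly), "year")])
  roster <- if (keep_roster) do.call(rbind, roster_rows) else NULL
  if (!is.null(roster)) roster <- roster[order(roster$patient_id, roster$year), ]
  structure(list(roster = roster, yearly = yearly, totals = totals,
                 n_patients = n_patients, seed = seed,
                 label = config$label),
            class = "fitreach_sim")
}

#' @export
print.fitreach_sim <- function(x, ...) {
  cat("<fitreach_sim> ", x$label, ": ", x$n_patients,
      " year-1 patients, seed ", x$seed, "\n", sep = "")
  cat(sprintf("  returned kits %d | screens %d | colonoscopies %d | CRC %d\n",
              x$totals[["returned_kits"]], x$totals[["unspoiled_screens"]],
              x$totals[["colonoscopies"]], x$totals[["crc_detected"]]))
  invisible(x)
}

#' Write a synthetic roster to CSV
#'
#' One row per active patient-year; the column schema is that of
#' `simulate_roster()$roster`. Reading the file back with [read_roster()]
#' reproduces the roster exactly.
#'
#' @param roster A `fitreach_sim` or its roster tibble (must be non-empty).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  if (inherits(roster, "fitreach_sim")) roster <- roster$roster
  stopifnot(is.data.frame(roster))
  utils::write.csv(roster, path, row.names = FALSE)
  invisible(path)
}

#' Read a synthetic roster from CSV
#'
#' @param path CSV path written by [write_roster()].
#' @return Roster tibble with the documented column types.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "integer",
                                       entry_year = "integer",
                                       year = "integer",
                                       mailed = "logical",
                                       returned = "logical",
                                       positive = "logical",
                                       navigated = "logical",
                                       crc_detected = "logical",
                                       opted_out = "logical"))
  tibble::as_tibble(df)
}
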