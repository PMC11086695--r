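#' Parameter containers for the mailed-FIT outreach model
#'
#' Constructors for the typed parameter blocks that make up a
#' [model_config()]: the eligible cohort, screening behavior, unit costs,
#' organizational configuration, and cancer-prevention coefficients. Each
#' constructor validates its arguments and every validation failure names the
#' offending field.
#'
#' @name fitreach-params
NULL

.assert_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single fraction in [0, 1] (got %s)",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.numeric(x)
}

.assert_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative number (got %s)",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.numeric(x)
}

.assert_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                 field, min, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.integer(round(x))
}

#' @describeIn fitreach-params Size and growth of the unscreened, age-eligible
#'   patient population.
#' @param initial_unscreened Number of unscreened, age-eligible patients in
#'   program year 1 (the year-1 mailing pool).
#' @param annual_growth Annual growth of the eligible cohort, as a fraction
#'   per year. New entrants receive their first mailing in their entry year.
#' @param horizon Program horizon in years (integer, >= 1).
#' @param uninsured_fraction Fraction of the unscreened population without
#'   health insurance; the payer covers colonoscopy for these patients.
#' @param growth_compounding If `TRUE` (default) entrants in year t are
#'   `initial_unscreened * annual_growth * (1 + annual_growth)^(t - 2)`;
#'   if `FALSE`, a constant `initial_unscreened * annual_growth` per year.
#' @export
cohort_params <- function(initial_unscreened = 215000,
                          annual_growth = 0.05,
                          horizon = 5L,
                          uninsured_fraction = 0.39,
                          growth_compounding = TRUE) {
  out <- list(
    initial_unscreened = .assert_nonneg(initial_unscreened, "initial_unscreened"),
    annual_growth = .assert_fraction(annual_growth, "annual_growth"),
    horizon = .assert_count(horizon, "horizon", min = 1L),
    uninsured_fraction = .assert_fraction(uninsured_fraction, "uninsured_fraction"),
    growth_compounding = isTRUE(growth_compounding)
  )
  structure(out, class = "fitreach_cohort_params")
}

#' @describeIn fitreach-params Screening behavior: return, spoilage,
#'   positivity, navigation and detection rates.
#' @param first_return_rate Fraction of patients who return the FIT in the
#'   year of their first mailing.
#' @param conditional_return Named numeric vector of return probabilities for
#'   patients with at least one year of mailing history, keyed by
#'   `"<yes|no>_<k>"` where `yes`/`no` records whether the patient returned a
#'   kit in the previous year and `k` is the number of prior returned kits
#'   (e.g. `"yes_1"`, `"no_0"`). Missing keys fall back to the entry with the
#'   same last-year flag and the largest available `k` not exceeding the
#'   requested one. Defaults to the package's reconstructed calibration,
#'   [default_conditional_return()].
#' @param history_overrides Optional named numeric vector of return
#'   probabilities keyed by full history strings (e.g. `"RN"` for
#'   returned-then-missed); takes precedence over `conditional_return`.
#' @param reminder_fraction Fraction of mailed patients who require a reminder
#'   letter.
#' @param optout_rate Fraction of mailed non-returners who opt out of future
#'   mailings each year (base case 0; opting out is absorbing).
#' @param postcard_return_rate Fraction of mailed patients who return the
#'   records-update postcard (base case 0).
#' @param positivity_initial,positivity_later FIT positivity among processed
#'   (unspoiled) screens in the initial period and thereafter.
#' @param positivity_mode `"by_program_year"` (default): `positivity_initial`
#'   applies in program year 1 and `positivity_later` in years 2+.
#'   `"by_screen_round"`: `positivity_initial` applies to a patient's first
#'   returned kit, `positivity_later` to repeat screens.
#' @param crc_detection_rate Fraction of completed colonoscopies that detect
#'   colorectal cancer.
#' @param adenoma_detection_rate Fraction of completed colonoscopies that
#'   detect adenomas.
#' @export
behavior_params <- function(first_return_rate = 0.19,
                            conditional_return = default_conditional_return(),
                            history_overrides = NULL,
                            reminder_fraction = 0.83,
                            optout_rate = 0,
                            postcard_return_rate = 0,
                            positivity_initial = 0.06,
                            positivity_later = 0.05,
                            positivity_mode = c("by_program_year", "by_screen_round"),
                            crc_detection_rate = 0.045,
                            adenoma_detection_rate = 0.39) {
  positivity_mode <- match.arg(positivity_mode)
  conditional_return <- unlist(conditional_return)
  if (length(conditional_return) == 0 || is.null(names(conditional_return)) ||
      any(!nzchar(names(conditional_return)))) {
    stop("`conditional_return` must be a non-empty named numeric vector",
         call. = FALSE)
  }
  if (!all(grepl("^(yes|no)_[0-9]+$", names(conditional_return)))) {
    stop("`conditional_return` names must match \"<yes|no>_<k>\"", call. = FALSE)
  }
  for (nm in names(conditional_return)) {
    .assert_fraction(conditional_return[[nm]], paste0("conditional_return[", nm, "]"))
  }
  if (!is.null(history_overrides)) {
    history_overrides <- unlist(history_overrides)
    if (is.null(names(history_overrides)) ||
        !all(grepl("^[RN]+$", names(history_overrides)))) {
      stop("`history_overrides` must be named by history strings of R/N",
           call. = FALSE)
    }
    for (nm in names(history_overrides)) {
      .assert_fraction(history_overrides[[nm]], paste0("history_overrides[", nm, "]"))
    }
  }
  out <- list(
    first_return_rate = .assert_fraction(first_return_rate, "first_return_rate"),
    conditional_return = conditional_return,
    history_overrides = history_overrides,
    reminder_fraction = .assert_fraction(reminder_fraction, "reminder_fraction"),
    optout_rate = .assert_fraction(optout_rate, "optout_rate"),
    postcard_return_rate = .assert_fraction(postcard_return_rate, "postcard_return_rate"),
    positivity_initial = .assert_fraction(positivity_initial, "positivity_initial"),
    positivity_later = .assert_fraction(positivity_later, "positivity_later"),
    positivity_mode = positivity_mode,
    crc_detection_rate = .assert_fraction(crc_detection_rate, "crc_detection_rate"),
    adenoma_detection_rate = .assert_fraction(adenoma_detection_rate, "adenoma_detection_rate")
  )
  structure(out, class = "fitreach_behavior_params")
}

#' @describeIn fitreach-params Direct unit costs (2022 US$). Navigation and
#'   positive-call costs are derived from staff wages and task minutes; see
#'   [labor_cost()].
#' @param mailer Cost per FIT mailing packet.
#' @param reminder_letter Cost per reminder letter.
#' @param text_setup One-time automated-text set-up cost per mailing site.
#' @param results_letter Cost per results letter (one per processed screen).
#' @param postcard_processing Cost per returned records-update postcard.
#' @param reply_mail_annual Annual business-reply-mail fee per mailing site.
#' @param fit_processing Laboratory fee per returned kit (overridden by the
#'   organizational configuration's `fit_fee`).
#' @param update_result Cost to record a processed FIT result in the EHR.
#' @param positive_call Cost of the telephone call for a positive result.
#' @param navigator_wage,clerical_wage Hourly wages used to derive
#'   time-priced tasks.
#' @param colonoscopy Cost per colonoscopy.
#' @export
unit_costs <- function(mailer = 6.73,
                       reminder_letter = 1.15,
                       text_setup = 78.95,
                       results_letter = 1.15,
                       postcard_processing = 3.96,
                       reply_mail_annual = 275,
                       fit_processing = 20,
                       update_result = 0.97,
                       positive_call = 3.96,
                       navigator_wage = 39.59,
                       clerical_wage = 29.22,
                       colonoscopy = 1800) {
  fields <- list(mailer = mailer, reminder_letter = reminder_letter,
                 text_setup = text_setup, results_letter = results_letter,
                 postcard_processing = postcard_processing,
                 reply_mail_annual = reply_mail_annual,
                 fit_processing = fit_processing, update_result = update_result,
                 positive_call = positive_call, navigator_wage = navigator_wage,
                 clerical_wage = clerical_wage, colonoscopy = colonoscopy)
  out <- mapply(.assert_nonneg, fields, names(fields), SIMPLIFY = FALSE)
  structure(out, class = "fitreach_unit_costs")
}

#' @describeIn fitreach-params Organizational configuration (centralized,
#'   hybrid, or regional) and the six parameters that distinguish them.
#' @param name One of `"centralized"`, `"hybrid"`, `"regional"`, or
#'   `"custom"` for a hand-built configuration.
#' @param indirect_rate Ongoing indirect (overhead) cost as a fraction of
#'   ongoing non-colonoscopy cost.
#' @param startup_rate One-time start-up cost as a fraction of year-1
#'   non-colonoscopy cost (direct plus indirect).
#' @param unspoiled_rate Fraction of returned kits that can be processed.
#' @param navigation_success Fraction of positive results that lead to a
#'   completed colonoscopy.
#' @param fit_fee Laboratory processing fee per returned kit under this
#'   configuration.
#' @param navigation_minutes Navigator minutes per positive result.
#' @param n_mailing_sites,n_navigation_sites Number of mailing / navigation
#'   operations (7 each for regional, 1 mailing site otherwise).
#' @export
org_config <- function(name = c("centralized", "hybrid", "regional", "custom"),
                       indirect_rate = NULL,
                       startup_rate = NULL,
                       unspoiled_rate = NULL,
                       navigation_success = NULL,
                       fit_fee = NULL,
                       navigation_minutes = NULL,
                       n_mailing_sites = NULL,
                       n_navigation_sites = NULL) {
  name <- match.arg(name)
  base <- switch(name,
    centralized = list(indirect_rate = 0.15, startup_rate = 0.05,
                       unspoiled_rate = 0.90, navigation_success = 0.65,
                       fit_fee = 20, navigation_minutes = 18,
                       n_mailing_sites = 1L, n_navigation_sites = 1L),
    hybrid = list(indirect_rate = 0.20, startup_rate = 0.075,
                  unspoiled_rate = 0.90, navigation_success = 0.70,
                  fit_fee = 20, navigation_minutes = 15,
                  n_mailing_sites = 1L, n_navigation_sites = 7L),
    regional = list(indirect_rate = 0.24, startup_rate = 0.10,
                    unspoiled_rate = 0.95, navigation_success = 0.70,
                    fit_fee = 23, navigation_minutes = 15,
                    n_mailing_sites = 7L, n_navigation_sites = 7L),
    custom = list(indirect_rate = 0.20, startup_rate = 0.075,
                  unspoiled_rate = 0.90, navigation_success = 0.70,
                  fit_fee = 20, navigation_minutes = 15,
                  n_mailing_sites = 1L, n_navigation_sites = 1L)
  )
  user <- list(indirect_rate = indirect_rate, startup_rate = startup_rate,
               unspoiled_rate = unspoiled_rate,
               navigation_success = navigation_success, fit_fee = fit_fee,
               navigation_minutes = navigation_minutes,
               n_mailing_sites = n_mailing_sites,
               n_navigation_sites = n_navigation_sites)
  for (nm in names(user)) if (!is.null(user[[nm]])) base[[nm]] <- user[[nm]]
  out <- list(
    name = name,
    indirect_rate = .assert_fraction(base$indirect_rate, "indirect_rate"),
    startup_rate = .assert_fraction(base$startup_rate, "startup_rate"),
    unspoiled_rate = .assert_fraction(base$unspoiled_rate, "unspoiled_rate"),
    navigation_success = .assert_fraction(base$navigation_success, "navigation_success"),
    fit_fee = .assert_nonneg(base$fit_fee, "fit_fee"),
    navigation_minutes = .assert_nonneg(base$navigation_minutes, "navigation_minutes"),
    n_mailing_sites = .assert_count(base$n_mailing_sites, "n_mailing_sites", min = 1L),
    n_navigation_sites = .assert_count(base$n_navigation_sites, "n_navigation_sites", min = 1L)
  )
  structure(out, class = "fitreach_org_config")
}

#' @describeIn fitreach-params Linear coefficients mapping process volumes to
#'   cancers prevented and cancer deaths averted.
#' @param prevented_per_unit Cancers prevented per unit of the basis volume.
#' @param deaths_per_unit Cancer deaths averted per unit of the basis volume.
#' @param basis `"per_colonoscopy"` (default) applies the coefficients to
#'   completed colonoscopies; `"per_detected"` to detected cancers.
#' @export
prevention_coefficients <- function(prevented_per_unit = default_prevention()[["prevented_per_unit"]],
                                    deaths_per_unit = default_prevention()[["deaths_per_unit"]],
                                    basis = c("per_colonoscopy", "per_detected")) {
  basis <- match.arg(basis)
  out <- list(
    prevented_per_unit = .assert_nonneg(prevented_per_unit, "prevented_per_unit"),
    deaths_per_unit = .assert_nonneg(deaths_per_unit, "deaths_per_unit"),
    basis = basis
  )
  structure(out, class = "fitreach_prevention")
}

#' Admissible outreach strategies
#'
#' In year 1 every age-eligible unscreened patient is mailed a kit. In later
#' years kits go to all newly eligible patients plus, depending on strategy:
#' `"everyone"` - every patient previously mailed (who has not opted out or
#' tested positive); `"at_least_once"` - patients who returned a kit at least
#' once; `"previous_year"` - patients who returned a kit in the previous year.
#'
#' @return Character vector of the three strategy names.
#' @export
outreach_strategies <- function() c("everyone", "at_least_once", "previous_year")

#' Assemble a full model configuration
#'
#' Bundles the parameter blocks for one scenario: an outreach strategy run
#' under an organizational configuration. The organizational FIT fee
#' overrides `unit_costs$fit_processing` at costing time.
#'
#' @param strategy One of [outreach_strategies()].
#' @param org An [org_config()] or the name of a built-in configuration.
#' @param cohort A [cohort_params()].
#' @param behavior A [behavior_params()].
#' @param costs A [unit_costs()].
#' @param prevention A [prevention_coefficients()].
#' @param discount_rate Annual discount rate applied to cost and outcome
#'   flows; the base case is undiscounted (0).
#' @param label Optional scenario label; defaults to `"<strategy>_<org>"`.
#' @return A `fitreach_config` object.
#' @examples
#' cfg <- model_config("at_least_once", "hybrid")
#' cfg$org$indirect_rate   # 0.20
#' @export
model_config <- function(strategy = "at_least_once",
                         org = "hybrid",
                         cohort = cohort_params(),
                         behavior = behavior_params(),
                         costs = unit_costs(),
                         prevention = prevention_coefficients(),
                         discount_rate = 0,
                         label = NULL) {
  strategy <- tolower(strategy)
  if (!strategy %in% outreach_strategies()) {
    stop(sprintf("`strategy` must be one of %s (got \"%s\")",
                 paste(dQuote(outreach_strategies(), FALSE), collapse = ", "),
                 strategy), call. = FALSE)
  }
  if (is.character(org)) org <- org_config(org)
  stopifnot(inherits(org, "fitreach_org_config"),
            inherits(cohort, "fitreach_cohort_params"),
            inherits(behavior, "fitreach_behavior_params"),
            inherits(costs, "fitreach_unit_costs"),
            inherits(prevention, "fitreach_prevention"))
  discount_rate <- .assert_fraction(discount_rate, "discount_rate")
  if (is.null(label)) label <- paste(strategy, org$name, sep = "_")
  structure(list(strategy = strategy, org = org, cohort = cohort,
                 behavior = behavior, costs = costs, prevention = prevention,
                 discount_rate = discount_rate, label = label),
            class = "fitreach_config")
}

#' @export
print.fitreach_config <- function(x, ...) {
  cat("<fitreach_config> ", x$label, "\n", sep = "")
  cat("  strategy: ", x$strategy, " | org: ", x$org$name,
      " | horizon: ", x$cohort$horizon, " y\n", sep = "")
  cat("  cohort: ", format(x$cohort$initial_unscreened, big.mark = ","),
      " unscreened, growth ", sprintf("%.1f%%", 100 * x$cohort$annual_growth),
      "/y, uninsured ", sprintf("%.0f%%", 100 * x$cohort$uninsured_fraction),
      "\n", sep = "")
  cat("  org: indirect ", sprintf("%.1f%%", 100 * x$org$indirect_rate),
      ", start-up ", sprintf("%.1f%%", 100 * x$org$startup_rate),
      ", unspoiled ", sprintf("%.0f%%", 100 * x$org$unspoiled_rate),
      ", navigation ", sprintf("%.0f%%", 100 * x$org$navigation_success),
      ", FIT fee $", format(x$org$fit_fee),
      ", ", x$org$navigation_minutes, " min\n", sep = "")
  invisible(x)
}

#' Price a timed staff task
#'
#' Unit costs for letter preparation, EHR updates, result calls and
#' colonoscopy navigation are priced as an hourly wage times task minutes,
#' rounded to the cent. For example a 15-minute navigation task at the
#' navigator wage of $39.59/h costs $9.90, and an 18-minute task $11.88.
#'
#' @param wage Hourly wage in dollars.
#' @param minutes Task duration in minutes.
#' @param round_cents Round to the nearest cent (default `TRUE`).
#' @return Cost in dollars.
#' @export
labor_cost <- function(wage, minutes, round_cents = TRUE) {
  x <- wage * minutes / 60
  if (round_cents) round(x, 2) else x
}
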