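#' Program costing
#'
#' Yearly process volumes are converted into dollars in four layers: direct
#' costs (per-unit intervention costs plus fixed per-site fees), indirect
#' overhead (a fixed fraction of direct cost), a one-time start-up cost (a
#' fixed fraction of year-1 direct plus indirect cost), and the payer's
#' colonoscopy cost for uninsured patients. Colonoscopy costs are excluded
#' from the overhead and start-up bases. All amounts are real dollars; the
#' base case is undiscounted.
#'
#' @name fitreach-costing
NULL

#' Direct cost of one program year, by line item
#'
#' Line items: FIT mailers, reminder letters, results letters (one per
#' processed screen), laboratory processing of every returned kit (at the
#' organizational FIT fee, spoiled kits included), EHR result updates (one
#' per processed screen), calls about positive results, navigator time per
#' positive (wage x minutes), processing of returned records-update
#' postcards, a one-time automated-text set-up per mailing site in year 1,
#' and the annual business-reply-mail fee per mailing site.
#'
#' @param volumes One-row tibble (or list) of year volumes as produced by
#'   [advance_year()].
#' @param costs A [unit_costs()].
#' @param org An [org_config()]; supplies the FIT fee, navigation minutes and
#'   the number of mailing sites.
#' @param year Program year (the text set-up is charged in year 1 only).
#' @return Named numeric vector of dollar amounts by line item.
#' @examples
#' v <- run_scenario(model_config("at_least_once", "hybrid"))$yearly[1, ]
#' sum(direct_cost(v, unit_costs(), org_config("hybrid"), year = 1))
#' @export
direct_cost <- function(volumes, costs, org, year) {
  stopifnot(inherits(costs, "fitreach_unit_costs"),
            inherits(org, "fitreach_org_config"))
  navigation_unit <- labor_cost(costs$navigator_wage, org$navigation_minutes,
                                round_cents = FALSE)
  c(
    mailers = volumes$mailed * costs$mailer,
    reminders = volumes$reminders * costs$reminder_letter,
    text_setup = if (year == 1) costs$text_setup * org$n_mailing_sites else 0,
    results_letters = volumes$unspoiled_screens * costs$results_letter,
    fit_processing = volumes$returned_kits * org$fit_fee,
    result_updates = volumes$unspoiled_screens * costs$update_result,
    positive_calls = volumes$positives * costs$positive_call,
    navigation = volumes$positives * navigation_unit,
    postcards = volumes$postcards_returned * costs$postcard_processing,
    reply_mail = costs$reply_mail_annual * org$n_mailing_sites
  )
}

#' Payer cost of follow-up colonoscopy
#'
#' The payer covers colonoscopy only for patients without health insurance.
#'
#' @param colonoscopies Number of completed colonoscopies.
#' @param cohort A [cohort_params()] (supplies `uninsured_fraction`).
#' @param costs A [unit_costs()] (supplies the colonoscopy price).
#' @return Dollar amount.
#' @examples
#' payer_colonoscopy_cost(1000, cohort_params(), unit_costs())  # 702000
#' @export
payer_colonoscopy_cost <- function(colonoscopies, cohort, costs) {
  stopifnot(colonoscopies >= 0)
  colonoscopies * cohort$uninsured_fraction * costs$colonoscopy
}

#' Indirect overhead and start-up cost
#'
#' Indirect cost in each year is `indirect_rate` times that year's direct
#' (non-colonoscopy) cost. The one-time start-up cost is `startup_rate`
#' times year-1 ongoing cost, i.e. year-1 direct plus year-1 indirect,
#' colonoscopies excluded.
#'
#' @param direct_by_year Numeric vector of yearly direct costs (colonoscopy
#'   costs excluded).
#' @param org An [org_config()].
#' @return List with `indirect_by_year` (numeric vector) and `startup`
#'   (scalar).
#' @export
apply_overheads <- function(direct_by_year, org) {
  stopifnot(inherits(org, "fitreach_org_config"))
  indirect <- org$indirect_rate * direct_by_year
  startup <- org$startup_rate * (direct_by_year[1] + indirect[1])
  list(indirect_by_year = indirect, startup = startup)
}

.discount_factors <- function(n_years, rate) 1 / (1 + rate)^(seq_len(n_years) - 1)

#' Full cost breakdown for a scenario
#'
#' Assembles direct line items, indirect overhead, start-up and payer
#' colonoscopy costs for every program year and totals them, applying the
#' configured annual discount rate to yearly flows (start-up is a year-1
#' flow; the base case is undiscounted).
#'
#' @param config A [model_config()].
#' @param volumes A `fitreach_volumes` from [run_scenario()].
#' @return A `fitreach_costs` object: list with `yearly` (tibble: year, line
#'   items, `direct_total`, `indirect`, `colonoscopy_payer`), `startup`,
#'   `total` (discounted grand total) and `discount_rate`.
#' @examples
#' cfg <- model_config("at_least_once", "hybrid")
#' cc <- total_cost(cfg, run_scenario(cfg))
#' cc$total / 1e6
#' @export
total_cost <- function(config, volumes) {
  stopifnot(inherits(config, "fitreach_config"),
            inherits(volumes, "fitreach_volumes"))
  yearly <- volumes$yearly
  n <- nrow(yearly)
  items <- t(vapply(seq_len(n), function(i) {
    direct_cost(yearly[i, ], config$costs, config$org, year = yearly$year[i])
  }, numeric(10)))
  direct_total <- rowSums(items)
  oh <- apply_overheads(direct_total, config$org)
  payer <- payer_colonoscopy_cost(yearly$colonoscopies, config$cohort,
                                  config$costs)
  df <- tibble::as_tibble(cbind(data.frame(year = yearly$year), items))
  df$direct_total <- direct_total
  df$indirect <- oh$indirect_by_year
  df$colonoscopy_payer <- payer
  disc <- .discount_factors(n, config$discount_rate)
  total <- oh$startup +
    sum((direct_total + oh$indirect_by_year + payer) * disc)
  structure(list(label = config$label, yearly = df, startup = oh$startup,
                 total = total, discount_rate = config$discount_rate),
            class = "fitreach_costs")
}

#' @export
print.fitreach_costs <- function(x, ...) {
  cat("<fitreach_costs> ", x$label, "\n", sep = "")
  cat(sprintf("  start-up $%.0f | direct $%.0f | indirect $%.0f | colonoscopy (payer) $%.0f\n",
              x$startup, sum(x$yearly$direct_total), sum(x$yearly$indirect),
              sum(x$yearly$colonoscopy_payer)))
  cat(sprintf("  5-year total $%.2f million (discount rate %.1f%%)\n",
              x$total / 1e6, 100 * x$discount_rate))
  invisible(x)
}
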