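#' Scenario pipeline and published-style tables
#'
#' [evaluate_scenario()] chains the cohort engine, costing and outcome
#' projection for one configuration; [run_scenarios()] evaluates a set of
#' configurations (the nine defaults unless told otherwise) and
#' [scenario_summary()] collects totals into one row per scenario.
#' [cea_table()] and [acer_table()] reproduce the two summary-table layouts
#' used for reporting: the frontier/ICER table and the fixed-budget ACER
#' table.
#'
#' @name fitreach-report
NULL

#' Evaluate one scenario end to end
#'
#' @param config A [model_config()].
#' @return A `fitreach_result`: list with `label`, `config`, `volumes`
#'   (from [run_scenario()]), `costs` (from [total_cost()]), `outcomes`
#'   (from [project_outcomes()]) and scalar `total_cost`.
#' @examples
#' res <- evaluate_scenario(model_config("at_least_once", "hybrid"))
#' res$total_cost / 1e6
#' @export
evaluate_scenario <- function(config) {
  volumes <- run_scenario(config)
  costs <- total_cost(config, volumes)
  outcomes <- project_outcomes(volumes, config$prevention, config$behavior,
                               discount_rate = config$discount_rate)
  structure(list(label = config$label, config = config, volumes = volumes,
                 costs = costs, outcomes = outcomes,
                 total_cost = costs$total),
            class = "fitreach_result")
}

#' @export
print.fitreach_result <- function(x, ...) {
  o <- x$outcomes
  cat("<fitreach_result> ", x$label, "\n", sep = "")
  cat(sprintf("  cost $%.1fM | screens %.1fK | colonoscopies %.2fK\n",
              x$total_cost / 1e6, o[["screens"]] / 1e3,
              o[["colonoscopies"]] / 1e3))
  cat(sprintf("  CRC detected %.0f | prevented %.0f | deaths averted %.0f\n",
              o[["crc_detected"]], o[["crc_prevented"]],
              o[["crc_deaths_prevented"]]))
  invisible(x)
}

#' Evaluate a list of scenarios
#'
#' @param configs Named list of [model_config()] objects; defaults to the
#'   nine built-in scenarios.
#' @return Named list of `fitreach_result` objects.
#' @export
run_scenarios <- function(configs = default_scenarios()) {
  stopifnot(length(configs) >= 1)
  lapply(configs, evaluate_scenario)
}

#' One-row-per-scenario summary of costs and outcomes
#'
#' @param results List of `fitreach_result` objects from [run_scenarios()].
#' @param include_no_program Prepend the zero-cost, zero-effect comparator
#'   row (default `TRUE`).
#' @return Tibble with columns `label`, `strategy`, `org`, `cost`,
#'   `crc_detected`, `crc_prevented`, `crc_deaths_prevented`, `screens`,
#'   `colonoscopies` (raw units: dollars and counts).
#' @export
scenario_summary <- function(results, include_no_program = TRUE) {
  rows <- lapply(results, function(r) {
    o <- r$outcomes
    tibble::tibble(label = r$label, strategy = r$config$strategy,
                   org = r$config$org$name, cost = r$total_cost,
                   crc_detected = o[["crc_detected"]],
                   crc_prevented = o[["crc_prevented"]],
                   crc_deaths_prevented = o[["crc_deaths_prevented"]],
                   screens = o[["screens"]],
                   colonoscopies = o[["colonoscopies"]])
  })
  out <- do.call(rbind, rows)
  if (include_no_program) {
    anchor <- no_program()
    anchor$strategy <- "none"; anchor$org <- "none"
    out <- rbind(anchor[, names(out)], out)
  }
  out
}

#' Frontier/ICER table across scenarios
#'
#' Runs [dominance_frontier()] once per outcome column and merges the
#' results: each outcome contributes a dominance status and an ICER column.
#' Dominated options are labelled `"SD"`/`"WD"` in published style when
#' `paper_style = TRUE`, which also rounds costs to $0.1M and outcome counts
#' to published precision.
#'
#' @param summary Tibble from [scenario_summary()] (anchor row included).
#' @param outcomes Character vector of outcome columns to analyse.
#' @param paper_style Return rounded, publication-style values
#'   (default `FALSE`: full precision).
#' @return Tibble with one row per option and, per outcome, `status_<k>` and
#'   `icer_<k>` columns (ICERs in dollars per outcome unit).
#' @export
cea_table <- function(summary,
                      outcomes = c("crc_detected", "crc_prevented",
                                   "crc_deaths_prevented"),
                      paper_style = FALSE) {
  stopifnot(all(c("label", "cost") %in% names(summary)),
            all(outcomes %in% names(summary)))
  out <- summary
  for (k in outcomes) {
    fr <- dominance_frontier(tibble::tibble(label = summary$label,
                                            cost = summary$cost,
                                            effect = summary[[k]]))
    m <- match(out$label, fr$label)
    out[[paste0("status_", k)]] <- fr$status[m]
    out[[paste0("icer_", k)]] <- fr$icer[m]
  }
  if (paper_style) {
    out$cost <- round(out$cost / 1e6, 1)
    for (k in outcomes) {
      out[[k]] <- round(out[[k]])
      ic <- out[[paste0("icer_", k)]] / 1e3
      st <- out[[paste0("status_", k)]]
      out[[paste0("icer_", k)]] <-
        ifelse(st == "weakly_dominated", "WD",
               ifelse(st == "strictly_dominated", "SD",
                      ifelse(is.na(ic), "-", sprintf("%.1f", ic))))
    }
    if ("screens" %in% names(out)) out$screens <- round(out$screens / 1e3, 1)
    if ("colonoscopies" %in% names(out))
      out$colonoscopies <- round(out$colonoscopies / 1e3, 1)
  }
  out
}

#' Fixed-budget ACER table across scenarios
#'
#' @param results List of `fitreach_result` objects.
#' @param budget Fixed budget in dollars (default $5 million).
#' @param paper_style Round outcomes and report ACERs in thousands of
#'   dollars (default `FALSE`).
#' @return Tibble: one row per scenario with budget-scaled outcomes and an
#'   `acer_<k>` column (dollars per outcome unit) for each outcome.
#' @export
acer_table <- function(results, budget = 5e6, paper_style = FALSE) {
  rows <- lapply(results, function(r) {
    a <- acer_fixed_budget(r, budget)
    sc <- a$scaled_outcomes; ac <- a$acers
    tibble::tibble(label = r$label, strategy = r$config$strategy,
                   org = r$config$org$name,
                   crc_detected = sc[["crc_detected"]],
                   crc_prevented = sc[["crc_prevented"]],
                   crc_deaths_prevented = sc[["crc_deaths_prevented"]],
                   screens = sc[["screens"]],
                   colonoscopies = sc[["colonoscopies"]],
                   acer_crc_detected = ac[["crc_detected"]],
                   acer_crc_prevented = ac[["crc_prevented"]],
                   acer_crc_deaths_prevented = ac[["crc_deaths_prevented"]])
  })
  out <- do.call(rbind, rows)
  if (paper_style) {
    for (k in c("crc_detected", "crc_prevented", "crc_deaths_prevented"))
      out[[k]] <- round(out[[k]], 1)
    out$screens <- round(out$screens / 1e3, 1)
    out$colonoscopies <- round(out$colonoscopies / 1e3, 2)
    for (k in paste0("acer_", c("crc_detected", "crc_prevented",
                                "crc_deaths_prevented")))
      out[[k]] <- round(out[[k]] / 1e3, 1)
  }
  out
}

#' Write scenario results to disk with a run manifest
#'
#' Writes per-year volumes and cost line items as tidy CSV
#' (`scenario, year, metric, value`), the scenario summary as CSV, 5-year
#' totals as JSON, and a `manifest.json` recording the package version,
#' timestamp, configuration hashes and output paths, so every output file is
#' traceable to the run that produced it.
#'
#' @param results List of `fitreach_result` objects.
#' @param dir Output directory (created if missing).
#' @param seed Optional integer recorded in the manifest (for runs that also
#'   involve the stochastic simulator).
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(results, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tidy <- do.call(rbind, lapply(results, function(r) {
    y <- r$volumes$yearly
    long <- utils::stack(as.data.frame(y[, setdiff(names(y), "year")]))
    data.frame(scenario = r$label, year = rep(y$year, ncol(y) - 1L),
               metric = as.character(long$ind), value = long$values)
  }))
  volumes_path <- file.path(dir, "volumes.csv")
  utils::write.csv(tidy, volumes_path, row.names = FALSE)

  costs <- do.call(rbind, lapply(results, function(r) {
    y <- as.data.frame(r$costs$yearly)
    long <- utils::stack(y[, setdiff(names(y), "year")])
    data.frame(scenario = r$label, year = rep(y$year, ncol(y) - 1L),
               line_item = as.character(long$ind), dollars = long$values)
  }))
  costs_path <- file.path(dir, "costs.csv")
  utils::write.csv(costs, costs_path, row.names = FALSE)

  summary <- scenario_summary(results)
  summary_path <- file.path(dir, "summary.csv")
  utils::write.csv(summary, summary_path, row.names = FALSE)

  totals <- lapply(results, function(r) {
    list(total_cost = r$total_cost, startup = r$costs$startup,
         outcomes = as.list(unclass(r$outcomes)))
  })
  totals_path <- file.path(dir, "totals.json")
  jsonlite::write_json(totals, totals_path, auto_unbox = TRUE, digits = NA)

  manifest <- run_manifest(results, seed = seed,
                           outputs = c(volumes_path, costs_path,
                                       summary_path, totals_path))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Build a run manifest
#'
#' @param results List of `fitreach_result` objects.
#' @param seed Optional integer seed to record.
#' @param outputs Character vector of output paths to record.
#' @return List with package version, timestamp, per-scenario configuration
#'   hashes, seed and outputs.
#' @export
run_manifest <- function(results, seed = NULL, outputs = character()) {
  hashes <- vapply(results, function(r) {
    f <- tempfile(fileext = ".yaml")
    on.exit(unlink(f), add = TRUE)
    save_config(r$config, f)
    unname(tools::md5sum(f))
  }, character(1))
  list(package = "fitreach",
       version = as.character(utils::packageVersion("fitreach")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       seed = seed,
       config_md5 = as.list(hashes),
       outputs = outputs)
}
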