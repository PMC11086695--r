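#' Configuration file I/O
#'
#' A scenario is described by a single human-editable YAML file. Every field
#' is optional except where noted: omitted fields take the package defaults,
#' so a scenario file only needs the overrides that make it different (the
#' nine shipped scenarios differ in `strategy` and the six organizational
#' parameters only). The schema mirrors the constructor arguments of
#' [model_config()] and its blocks; see the packaged examples under
#' `system.file("extdata", "scenarios", package = "fitreach")` and the
#' README for the full field list with units.
#'
#' @name fitreach-config-io
NULL

.block_constructors <- function() {
  list(cohort = cohort_params, behavior = behavior_params,
       costs = unit_costs, org = org_config, prevention = prevention_coefficients)
}

.build_block <- function(block, values, fname) {
  ctor <- .block_constructors()[[block]]
  if (is.null(values)) return(ctor())
  if (!is.list(values)) {
    stop(sprintf("config block `%s` must be a mapping (in %s)", block, fname),
         call. = FALSE)
  }
  known <- names(formals(ctor))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown field(s) in config block `%s`: %s (in %s)",
                 block, paste(unknown, collapse = ", "), fname), call. = FALSE)
  }
  if (block == "behavior" && !is.null(values$conditional_return)) {
    values$conditional_return <- unlist(values$conditional_return)
  }
  if (block == "behavior" && !is.null(values$history_overrides)) {
    values$history_overrides <- unlist(values$history_overrides)
  }
  do.call(ctor, values)
}

#' Load a scenario configuration from YAML
#'
#' @param path Path to a YAML scenario file.
#' @return A validated [model_config()]; omitted fields are filled with
#'   package defaults. Any out-of-range or unknown field raises an error
#'   naming the field.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("label", "strategy", "discount_rate", "cohort", "behavior",
                 "costs", "org", "prevention")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    stop(sprintf("unknown top-level config field(s): %s (in %s)",
                 paste(unknown, collapse = ", "), path), call. = FALSE)
  }
  blocks <- lapply(stats::setNames(nm = names(.block_constructors())),
                   function(b) .build_block(b, raw[[b]], path))
  model_config(
    strategy = if (is.null(raw$strategy)) "at_least_once" else raw$strategy,
    org = blocks$org,
    cohort = blocks$cohort,
    behavior = blocks$behavior,
    costs = blocks$costs,
    prevention = blocks$prevention,
    discount_rate = if (is.null(raw$discount_rate)) 0 else raw$discount_rate,
    label = raw$label
  )
}

#' Save a scenario configuration to YAML
#'
#' Writes the fully expanded configuration (all fields, not just overrides)
#' so the file is self-contained; `load_config(save_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A [model_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "fitreach_config"))
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  }
  out <- list(
    label = config$label,
    strategy = config$strategy,
    discount_rate = config$discount_rate,
    cohort = strip(config$cohort),
    behavior = strip(config$behavior),
    costs = strip(config$costs),
    org = strip(config$org),
    prevention = strip(config$prevention)
  )
  out$behavior$history_overrides <- if (is.null(config$behavior$history_overrides))
    NULL else as.list(config$behavior$history_overrides)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
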