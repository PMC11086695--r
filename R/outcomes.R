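#' Patient and process outcomes
#'
#' Three patient outcomes (cancers detected, cancers prevented, cancer
#' deaths averted) and two process outcomes (processed screens, completed
#' colonoscopies) are projected from the scenario's process volumes.
#' Detection comes directly from the colonoscopy detection rate; the two
#' prevention outcomes are linear in completed colonoscopies (or detected
#' cancers, configurable) with coefficients shipped as a calibration
#' artifact, because the natural-history models that generate them are out
#' of scope.
#'
#' @name fitreach-outcomes
NULL

#' Project outcomes from scenario volumes
#'
#' @param volumes A `fitreach_volumes` from [run_scenario()].
#' @param prevention A [prevention_coefficients()].
#' @param behavior A [behavior_params()] (supplies the detection rate used in
#'   the `"per_detected"` basis).
#' @param discount_rate Annual discount rate applied to yearly outcome flows
#'   (default 0, the base case).
#' @return A named numeric vector (class `fitreach_outcomes`) with elements
#'   `screens`, `colonoscopies`, `crc_detected`, `crc_prevented`,
#'   `crc_deaths_prevented`.
#' @examples
#' v <- run_scenario(model_config("at_least_once", "hybrid"))
#' project_outcomes(v, prevention_coefficients(), behavior_params())
#' @export
project_outcomes <- function(volumes, prevention, behavior,
                             discount_rate = 0) {
  stopifnot(inherits(volumes, "fitreach_volumes"),
            inherits(prevention, "fitreach_prevention"),
            inherits(behavior, "fitreach_behavior_params"))
  y <- volumes$yearly
  disc <- .discount_factors(nrow(y), discount_rate)
  screens <- sum(y$unspoiled_screens * disc)
  col <- sum(y$colonoscopies * disc)
  detected <- sum(y$crc_detected * disc)
  basis_volume <- switch(prevention$basis,
                         per_colonoscopy = col,
                         per_detected = detected)
  out <- c(screens = screens,
           colonoscopies = col,
           crc_detected = detected,
           crc_prevented = prevention$prevented_per_unit * basis_volume,
           crc_deaths_prevented = prevention$deaths_per_unit * basis_volume)
  structure(out, class = c("fitreach_outcomes", "numeric"))
}

#' Calibrate prevention coefficients against published scenario pairs
#'
#' Fits the linear coefficient `c` in `outcome = c * basis_volume` through
#' the origin, over a set of published (basis volume, outcome) pairs.
#' `method = "ols"` is regression through the origin
#' (`sum(x*y) / sum(x^2)`); `method = "minimax"` minimizes the largest
#' absolute residual (Chebyshev fit), which bounds the worst-case
#' reproduction error across scenarios and is the criterion used for the
#' shipped defaults.
#'
#' @param basis_volume Numeric vector, e.g. colonoscopy counts.
#' @param outcome Numeric vector of the same length, e.g. cancers prevented.
#' @param method `"minimax"` (default) or `"ols"`.
#' @return The fitted coefficient (outcome units per basis-volume unit).
#' @examples
#' ref <- reference_estimates()
#' calibrate_prevention(ref$colonoscopies_thousands * 1000, ref$crc_prevented)
#' @export
calibrate_prevention <- function(basis_volume, outcome,
                                 method = c("minimax", "ols")) {
  method <- match.arg(method)
  stopifnot(length(basis_volume) == length(outcome), length(outcome) >= 1,
            all(basis_volume > 0), all(outcome >= 0))
  if (method == "ols") {
    sum(basis_volume * outcome) / sum(basis_volume^2)
  } else {
    # Chebyshev fit: minimize max_i |y_i - c x_i|; the objective is convex
    # piecewise linear in c, so golden-section search over the ratio range.
    lo <- min(outcome / basis_volume)
    hi <- max(outcome / basis_volume)
    if (lo == hi) return(lo)
    f <- function(c) max(abs(outcome - c * basis_volume))
    stats::optimize(f, c(lo, hi), tol = 1e-12)$minimum
  }
}
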