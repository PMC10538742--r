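#' Analysis configuration
#'
#' Bundles every tunable of the Grey-Markov pipeline with its default. The
#' defaults are the conventions under which the packaged Michigan worked
#' example reproduces its reference results; each is documented in the methods
#' vignette.
#'
#' @param rho Distinguishing coefficient of the relational coefficient, in
#'   \[0, 1\]. Damps the global maximum discrepancy; 0.5 is the conventional
#'   choice.
#' @param screen_threshold Minimum relational grade for a factor to be kept.
#' @param n_states Number of equal-width residual states for the Markov
#'   correction (>= 2).
#' @param residual_denominator `"actual"` (default) or `"fitted"`: the
#'   denominator of the relative residual. Published grey-Markov count tables
#'   use the actual value.
#' @param forecast_base `"last_actual"` (default) or `"model_forecast"`: the
#'   base value the corrected out-of-sample forecast multiplies.
#' @param normalization `"initial"` (default) or `"mean"`: the dimensionless
#'   transform applied before relational analysis.
#' @param dimension_range Integer candidate counts of factor series for the
#'   model-dimension scan.
#' @param round_fitted Round fitted counts to integers (half away from zero)
#'   before residuals and error metrics are computed. Count data are reported
#'   as integers; this is the reporting-precision convention.
#' @param lookback Number of recent states summed (via k-step transitions)
#'   when predicting the next state.
#' @param coupling `"driven"` (default) or `"coupled"` multivariate grey
#'   model form; see [fit_mgm()].
#' @param seed Integer seed for synthetic runs (`NULL` for none).
#' @return A named list with class `grey_config`.
#' @export
grey_config <- function(rho = 0.5,
                        screen_threshold = 0.7,
                        n_states = 3,
                        residual_denominator = c("actual", "fitted"),
                        forecast_base = c("last_actual", "model_forecast"),
                        normalization = c("initial", "mean"),
                        dimension_range = 2:6,
                        round_fitted = TRUE,
                        lookback = 3,
                        coupling = c("driven", "coupled"),
                        seed = NULL) {
  check(is.numeric(rho) && length(rho) == 1 && rho >= 0 && rho <= 1,
        "`rho` must be a single number in [0, 1]", "config")
  check(is.numeric(n_states) && n_states >= 2,
        "`n_states` must be an integer >= 2", "config")
  check(is.numeric(lookback) && lookback >= 1,
        "`lookback` must be a positive integer", "config")
  check(is.numeric(dimension_range) && all(dimension_range >= 1),
        "`dimension_range` must be positive integers", "config")
  structure(
    list(
      rho = rho,
      screen_threshold = screen_threshold,
      n_states = as.integer(n_states),
      residual_denominator = match.arg(residual_denominator),
      forecast_base = match.arg(forecast_base),
      normalization = match.arg(normalization),
      dimension_range = as.integer(dimension_range),
      round_fitted = isTRUE(round_fitted),
      lookback = as.integer(lookback),
      coupling = match.arg(coupling),
      seed = seed
    ),
    class = "grey_config"
  )
}

#' Read a configuration from a YAML file
#'
#' Keys mirror the arguments of [grey_config()]; unknown keys fail loudly.
#' Values given in `...` (e.g. parsed command-line flags) override file
#' values.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param ... Overrides, as `key = value` pairs.
#' @return A `grey_config`.
#' @export
read_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    check(file.exists(path), sprintf("config file '%s' does not exist", path), "io")
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(grey_config))
  bad <- setdiff(names(vals), known)
  check(length(bad) == 0,
        sprintf("unknown configuration keys: %s", paste(bad, collapse = ", ")),
        "config")
  do.call(grey_config, vals)
}
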