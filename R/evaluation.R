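#' Forecast error metrics
#'
#' Mean absolute percentage error (reported on the percent scale, e.g. 4.47
#' for 4.47%), mean absolute error and root mean squared error (both in the
#' units of the series). All points enter the mean, including a zero-error
#' first point when the model anchors there.
#'
#' @param actual,predicted Numeric sequences of equal length; `mape()`
#'   additionally requires nonzero actual values.
#' @return A single number.
#' @examples
#' mape(c(100, 200), c(90, 210))
#' @export
mape <- function(actual, predicted) {
  check(length(actual) == length(predicted),
        "sequences must have equal length", "length")
  check(all(actual != 0), "MAPE undefined: zero actual value", "zero_divisor")
  mean(abs((actual - predicted) / actual)) * 100
}

#' @rdname mape
#' @export
mae <- function(actual, predicted) {
  check(length(actual) == length(predicted),
        "sequences must have equal length", "length")
  mean(abs(actual - predicted))
}

#' @rdname mape
#' @export
rmse <- function(actual, predicted) {
  check(length(actual) == length(predicted),
        "sequences must have equal length", "length")
  sqrt(mean((actual - predicted)^2))
}

#' Scan model dimension by fitted accuracy
#'
#' Fits an MGM(1,n) for each candidate number of factors n, taking the top-n
#' factors by relational grade, and records the dependent-series MAPE. The
#' selected dimension is the argmin (smallest n on ties). Candidate fits
#' whose estimation fails are recorded with `NA` and excluded from the
#' argmin, with a message in the returned table.
#'
#' @param panel A [grey_panel()].
#' @param relational A `grey_gra` from [grey_relate()]; its ranking orders
#'   the candidate factors (screened factors only).
#' @param n_range Candidate factor counts (default 2:6, capped at the number
#'   of kept factors).
#' @param coupling MGM form passed to [fit_mgm()].
#' @param round_fitted Reporting-precision convention for the MAPE.
#' @return A `grey_scan` tibble: `n_factors`, `factors`, `mape`, `note`;
#'   attribute `selected_n` holds the argmin, `fits` the per-n fits.
#' @examples
#' p <- michigan_roundabouts()
#' dimension_scan(p, grey_relate(p))
#' @export
dimension_scan <- function(panel, relational, n_range = 2:6,
                           coupling = c("driven", "coupled"),
                           round_fitted = TRUE) {
  coupling <- match.arg(coupling)
  check(inherits(relational, "grey_gra"), "`relational` must be a grey_gra",
        "input")
  pool <- relational$kept
  n_range <- n_range[n_range >= 1 & n_range <= length(pool)]
  check(length(n_range) >= 1, "no feasible dimension in `n_range`", "config")

  fits <- list()
  rows <- purrr::map(n_range, function(nn) {
    ids <- pool[seq_len(nn)]
    fit <- tryCatch(
      withCallingHandlers(
        fit_mgm(panel, factors = ids, coupling = coupling),
        greycast_warn_rank = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(tibble(n_factors = nn, factors = paste(ids, collapse = ","),
                    mape = NA_real_, note = conditionMessage(fit)))
    }
    fits[[as.character(nn)]] <<- fit
    f <- if (round_fitted) round_half_up(fit$fitted) else fit$fitted
    tibble(n_factors = nn, factors = paste(ids, collapse = ","),
           mape = mape(fit$actual, f), note = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  ok <- which(!is.na(out$mape))
  check(length(ok) >= 1, "every candidate dimension failed to fit", "all_failed")
  selected <- out$n_factors[ok[which.min(out$mape[ok])]]
  structure(out,
            selected_n = selected, fits = fits,
            class = c("grey_scan", class(tibble())))
}

#' Selected dimension of a scan
#' @param scan A `grey_scan` from [dimension_scan()].
#' @return The selected (argmin-MAPE) number of factors.
#' @export
selected_dimension <- function(scan) attr(scan, "selected_n")

#' @describeIn dimension_scan MAPE against candidate dimension.
#' @param object A `grey_scan`.
#' @param ... Unused.
#' @export
autoplot.grey_scan <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_factors, y = .data$mape)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = d[d$n_factors == selected_dimension(object), ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "number of factor series", y = "fitted MAPE (%)") +
    ggplot2::theme_minimal()
}

#' Compare GM(1,1), MGM(1,n) and the Markov-corrected model
#'
#' Runs the full comparison on one panel: grey relational screening, the
#' dimension scan, the selected MGM(1,n), its Markov correction, and a
#' GM(1,1) baseline on the dependent series alone; tabulates MAPE/MAE/RMSE
#' for all three models and the per-year fitted/corrected/error table.
#'
#' @param panel A [grey_panel()].
#' @param config A [grey_config()].
#' @return A `grey_comparison` object with `metrics` (one row per model),
#'   `by_year`, `scan`, `relational`, `fits` (list: gm11, mgm, markov).
#' @examples
#' cmp <- compare_models(michigan_roundabouts())
#' cmp$metrics
#' @export
compare_models <- function(panel, config = grey_config()) {
  rel <- grey_relate(panel, rho = config$rho,
                     threshold = config$screen_threshold,
                     normalization = config$normalization)
  scan <- dimension_scan(panel, rel, n_range = config$dimension_range,
                         coupling = config$coupling,
                         round_fitted = config$round_fitted)
  mgm <- attr(scan, "fits")[[as.character(selected_dimension(scan))]]
  mk <- markov_correct(mgm,
                       n_states = config$n_states,
                       lookback = config$lookback,
                       denominator = config$residual_denominator,
                       round_fitted = config$round_fitted,
                       forecast_base = config$forecast_base)
  gm <- fit_gm11(panel)

  rounder <- if (config$round_fitted) round_half_up else identity
  actual <- mgm$actual
  fits <- list(
    rounder(gm$fitted),
    rounder(mgm$fitted),
    mk$corrected
  )
  labels <- c(gm$label, mgm$label, paste0(mgm$label, "-Markov"))
  metrics <- purrr::map2_dfr(labels, fits, function(lb, f) {
    tibble(model = lb,
           mape = mape(actual, f), mae = mae(actual, f), rmse = rmse(actual, f))
  })
  by_year <- tibble(
    year = mgm$years, actual = actual,
    gm11 = fits[[1]], mgm = fits[[2]], corrected = fits[[3]],
    residual_mgm = mk$residuals, state = mk$states
  )
  structure(
    list(metrics = metrics, by_year = by_year, scan = scan, relational = rel,
         fits = list(gm11 = gm, mgm = mgm, markov = mk), config = config),
    class = "grey_comparison"
  )
}

#' @export
print.grey_comparison <- function(x, ...) {
  cat("Model comparison\n")
  print(dplyr::mutate(x$metrics, dplyr::across(dplyr::where(is.numeric),
                                               ~ round(.x, 2))))
  cat(sprintf("selected dimension: %d factors; corrected forecast %.0f\n",
              selected_dimension(x$scan), x$fits$markov$forecast))
  invisible(x)
}

#' @describeIn compare_models Per-model metric rows.
#' @param x A `grey_comparison`.
#' @param ... Unused.
#' @export
tidy.grey_comparison <- function(x, ...) x$metrics

#' @describeIn compare_models One-row overview.
#' @export
glance.grey_comparison <- function(x, ...) {
  tibble(
    n = nrow(x$by_year),
    selected_n = selected_dimension(x$scan),
    best_model = x$metrics$model[which.min(x$metrics$mape)],
    best_mape = min(x$metrics$mape),
    forecast = x$fits$markov$forecast
  )
}
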