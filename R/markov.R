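#' Relative residuals of a fitted series
#'
#' \eqn{\delta(k) = (x(k) - \hat x(k)) / x(k)} with the actual value in the
#' denominator (default), or \eqn{/\hat x(k)} under `denominator = "fitted"`.
#' Grey-Markov count tables conventionally use the actual-value form; the
#' fitted-value form is the literal residual of some formulations and has
#' the property that a midpoint-exact correction recovers the actual value
#' exactly.
#'
#' @param actual,fitted Numeric sequences of equal length.
#' @param denominator `"actual"` or `"fitted"`.
#' @return Numeric vector of dimensionless relative errors.
#' @examples
#' relative_residuals(c(1510, 1501), c(1308, 1653))
#' @export
relative_residuals <- function(actual, fitted,
                               denominator = c("actual", "fitted")) {
  denominator <- match.arg(denominator)
  check(length(actual) == length(fitted),
        "sequences must have equal length", "length")
  den <- if (denominator == "actual") actual else fitted
  check(all(den != 0), "zero denominator in relative residual", "zero_divisor")
  (actual - fitted) / den
}

#' Partition residuals into equal-width states
#'
#' Splits \[min residual, max residual\] into `s` equal-width intervals
#' \eqn{[L_j, U_j)}; the last interval is closed so the maximum residual is
#' assigned. State 1 collects the most negative residuals (overestimation of
#' the count), state `s` the most positive (underestimation).
#'
#' @param residuals Numeric residual sequence with at least two distinct
#'   values.
#' @param s Number of states (integer >= 2).
#' @return A `grey_states` tibble: `state`, `lower`, `upper`, `midpoint`.
#' @examples
#' partition_states(c(0, 0.1338, -0.1013, -0.0247, -0.0062, -0.0023), s = 3)
#' @export
partition_states <- function(residuals, s = 3) {
  check(is.numeric(s) && s >= 2, "`s` must be an integer >= 2", "config")
  lo <- min(residuals)
  hi <- max(residuals)
  check(hi > lo,
        "all residuals identical: zero-width states (model already exact)",
        "zero_width")
  edges <- lo + (hi - lo) * (0:s) / s
  edges[c(1, s + 1)] <- c(lo, hi)   # guard the extremes against fp drift
  structure(
    tibble(
      state = seq_len(s),
      lower = edges[-(s + 1)],
      upper = edges[-1],
      midpoint = (edges[-(s + 1)] + edges[-1]) / 2
    ),
    class = c("grey_states", class(tibble())),
    edges = edges
  )
}

#' Assign residuals to states
#'
#' Interval convention: \eqn{[L_j, U_j)} half-open, last interval closed, so
#' a residual sitting exactly on an interior boundary belongs to the upper
#' interval and the maximum residual to state `s`.
#'
#' @param residuals Numeric residual sequence.
#' @param bounds A `grey_states` partition from [partition_states()].
#' @return Integer state indices.
#' @export
assign_states <- function(residuals, bounds) {
  edges <- attr(bounds, "edges")
  eps <- 1e-9 * max(1, max(abs(edges)))   # fp slack at the extremes
  check(all(residuals >= edges[1] - eps &
              residuals <= edges[length(edges)] + eps),
        "residual outside state bounds", "out_of_bounds")
  residuals <- pmin(pmax(residuals, edges[1]), edges[length(edges)])
  findInterval(residuals, edges, rightmost.closed = TRUE)
}

#' Estimate the one-step transition matrix of a state sequence
#'
#' Counts adjacent state pairs \eqn{Q_{ij}} (the terminal state contributes
#' no source count) and normalizes rows by the source counts \eqn{Q_i}. A
#' state never visited as a source gets a uniform row (1/s each) with a
#' classed warning, so powers of the matrix stay row-stochastic.
#'
#' @param states Integer state sequence (length >= 2).
#' @param s Number of states; defaults to `max(states)`.
#' @return A list with `counts` (s x s matrix of \eqn{Q_{ij}}), `source`
#'   (\eqn{Q_i}), and `P1` (row-stochastic one-step matrix).
#' @examples
#' estimate_transitions(c(2, 3, 1, 1, 2, 2), s = 3)
#' @export
estimate_transitions <- function(states, s = max(states)) {
  check(length(states) >= 2, "need at least two states", "length")
  Q <- matrix(0, s, s)
  for (k in seq_len(length(states) - 1)) {
    Q[states[k], states[k + 1]] <- Q[states[k], states[k + 1]] + 1
  }
  src <- rowSums(Q)
  P1 <- Q / ifelse(src == 0, 1, src)
  if (any(src == 0)) {
    warn(sprintf("state(s) %s never observed as a source; using uniform rows",
                 paste(which(src == 0), collapse = ", ")),
         class = "greycast_warn_unvisited")
    P1[src == 0, ] <- 1 / s
  }
  list(counts = Q, source = src, P1 = P1)
}

#' k-step transition matrix
#'
#' By the Chapman-Kolmogorov equation the k-step matrix is the k-th matrix
#' power of the one-step matrix.
#'
#' @param P1 Row-stochastic one-step matrix.
#' @param k Positive integer number of steps.
#' @return The matrix power `P1^k`.
#' @export
kstep <- function(P1, k) {
  check(is.numeric(k) && length(k) == 1 && k >= 1, "`k` must be a positive integer",
        "horizon")
  out <- diag(nrow(P1))
  for (i in seq_len(k)) out <- out %*% P1
  out
}

#' Predict the next state from recent history
#'
#' For each step back k = 1..`lookback`, takes the row of the k-step matrix
#' indexed by the state observed k time points before the forecast target,
#' sums these row vectors columnwise, and picks the modal (largest-weight)
#' state. Ties are broken toward the lower state index, with a classed
#' warning.
#'
#' @param states Integer state sequence.
#' @param P1 One-step transition matrix.
#' @param lookback Number of recent states to use (>= 1, at most
#'   `length(states)`).
#' @return List with `table` (tibble: step, origin state, one row vector per
#'   step), `weights` (summed per-state weights) and `modal` (predicted
#'   state index).
#' @export
future_state_distribution <- function(states, P1, lookback = 3) {
  check(is.numeric(lookback) && lookback >= 1, "`lookback` must be >= 1", "horizon")
  check(lookback <= length(states), "`lookback` exceeds the state sequence",
        "length")
  s <- nrow(P1)
  rows <- purrr::map(seq_len(lookback), function(k) {
    origin <- states[length(states) - k + 1]
    w <- kstep(P1, k)[origin, ]
    tibble(step = k, origin = origin, state = seq_len(s), weight = w)
  })
  tab <- dplyr::bind_rows(rows)
  weights <- tapply(tab$weight, tab$state, sum)
  top <- which(weights == max(weights))
  if (length(top) > 1) {
    warn(sprintf("modal-state tie between states %s; choosing the lower index",
                 paste(top, collapse = ", ")),
         class = "greycast_warn_tie")
  }
  list(table = tab, weights = as.numeric(weights), modal = min(top))
}

#' Markov midpoint correction of fitted values
#'
#' Each fitted value whose residual lies in state j is multiplied by
#' \eqn{1 + (L_j + U_j)/2}, absorbing the systematic part of the fluctuation
#' the grey model misses. Applied to every in-sample point, including the
#' first.
#'
#' @param fitted Fitted sequence.
#' @param states Integer state per time point.
#' @param bounds A `grey_states` partition.
#' @return Corrected numeric sequence.
#' @export
correct_fitted <- function(fitted, states, bounds) {
  check(length(fitted) == length(states),
        "sequences must have equal length", "length")
  fitted * (1 + bounds$midpoint[states])
}

#' Corrected out-of-sample forecast
#'
#' Multiplies a base value by one plus the midpoint of the predicted modal
#' state. The conventional base is the last observed actual value
#' (`"last_actual"`); `"model_forecast"` uses a model-produced horizon-1
#' forecast instead.
#'
#' @param base_value The value being corrected.
#' @param state_bounds One row of a `grey_states` tibble (the modal state).
#' @return Corrected forecast value.
#' @export
forecast_corrected <- function(base_value, state_bounds) {
  base_value * (1 + state_bounds$midpoint[1])
}

#' Markov residual-state correction of a grey model fit
#'
#' Runs the full residual-correction chain on a fitted grey model: relative
#' residuals, equal-width state partition, state assignment, one-step
#' transition estimation, in-sample midpoint correction, modal-future-state
#' prediction (summing k-step rows over `lookback` recent states) and a
#' corrected next-period forecast.
#'
#' @param fit A `grey_fit` (usually from [fit_mgm()]).
#' @param n_states Number of residual states (default 3).
#' @param lookback Recent states used for the future-state vote (default 3).
#' @param denominator Residual denominator convention; see
#'   [relative_residuals()].
#' @param round_fitted Round fitted counts to integers before residuals
#'   (reporting-precision convention, default `TRUE`).
#' @param forecast_base `"last_actual"` or `"model_forecast"`.
#' @return A `grey_markov` object: `residuals`, `bounds`, `states`,
#'   `transitions` (counts, source, P1), `corrected`, `future` (weights,
#'   modal), `forecast` (corrected next value), plus the inputs.
#' @examples
#' fit <- fit_mgm(michigan_roundabouts(), c("X1", "X2", "X3", "X6"))
#' mk <- markov_correct(fit)
#' mk$forecast
#' @export
markov_correct <- function(fit, n_states = 3, lookback = 3,
                           denominator = c("actual", "fitted"),
                           round_fitted = TRUE,
                           forecast_base = c("last_actual", "model_forecast")) {
  denominator <- match.arg(denominator)
  forecast_base <- match.arg(forecast_base)
  check(inherits(fit, "grey_fit"), "`fit` must be a grey_fit", "input")

  fitted <- if (round_fitted) round_half_up(fit$fitted) else fit$fitted
  res <- relative_residuals(fit$actual, fitted, denominator)
  bounds <- partition_states(res, n_states)
  states <- assign_states(res, bounds)
  trans <- estimate_transitions(states, s = n_states)
  corrected <- correct_fitted(fitted, states, bounds)
  future <- future_state_distribution(states, trans$P1, lookback)

  base <- if (forecast_base == "last_actual") {
    fit$actual[fit$n]
  } else {
    fc <- forecast(fit, h = 1)
    if ("variable" %in% names(fc)) {
      fc$forecast[fc$variable == fit$variable_ids[1]]
    } else {
      fc$forecast[1]
    }
  }
  fc_corrected <- forecast_corrected(base, bounds[future$modal, ])

  structure(
    list(
      fit = fit,
      residuals = res, bounds = bounds, states = states,
      transitions = trans, corrected = corrected, future = future,
      forecast = fc_corrected, forecast_basis = base,
      n_states = n_states, lookback = lookback,
      denominator = denominator, round_fitted = round_fitted,
      forecast_base = forecast_base
    ),
    class = "grey_markov"
  )
}

#' @export
print.grey_markov <- function(x, ...) {
  cat(sprintf("Markov correction of %s (%d states)\n", x$fit$label, x$n_states))
  cat("state bounds:",
      paste(sprintf("%.4f", attr(x$bounds, "edges")), collapse = " / "), "\n")
  cat("state sequence:", paste0("S", x$states, collapse = " "), "\n")
  cat("one-step transition matrix:\n")
  print(MASS::fractions(x$transitions$P1))
  cat(sprintf("modal next state: S%d; corrected forecast %.1f (base %.0f)\n",
              x$future$modal, x$forecast, x$forecast_basis))
  invisible(x)
}

#' @describeIn markov_correct One row per year: actual, fitted, residual,
#'   state, corrected value.
#' @param x A `grey_markov` object.
#' @param ... Unused.
#' @export
tidy.grey_markov <- function(x, ...) {
  fitted <- if (x$round_fitted) round_half_up(x$fit$fitted) else x$fit$fitted
  tibble(
    year = x$fit$years, actual = x$fit$actual, fitted = fitted,
    residual = x$residuals, state = x$states, corrected = x$corrected
  )
}

#' @describeIn markov_correct One-row summary with corrected-series metrics.
#' @export
glance.grey_markov <- function(x, ...) {
  tibble(
    label = paste0(x$fit$label, "-Markov"), n = x$fit$n,
    n_states = x$n_states,
    mape = mape(x$fit$actual, x$corrected),
    mae = mae(x$fit$actual, x$corrected),
    rmse = rmse(x$fit$actual, x$corrected),
    modal_state = x$future$modal,
    forecast = x$forecast
  )
}

#' @describeIn markov_correct Actual vs fitted vs corrected series.
#' @param object A `grey_markov` object.
#' @export
autoplot.grey_markov <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("actual", "fitted", "corrected"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "year", y = "count", colour = NULL,
                  title = paste0(object$fit$label, "-Markov correction")) +
    ggplot2::theme_minimal()
}
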