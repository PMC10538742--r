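#' First-order accumulated generation (AGO)
#'
#' The accumulated generating operation turns a raw non-negative series into
#' its cumulative sum \eqn{x^{(1)}(k) = \sum_{p \le k} x^{(0)}(p)}, which is
#' near-exponential for count data with a trend and is the series the grey
#' differential equations are written for. The background sequence is the
#' adjacent mean \eqn{z(k) = (x^{(1)}(k) + x^{(1)}(k-1))/2}, defined for
#' k = 2..n, and is the regressor of the grey least-squares stage.
#'
#' @param x A non-empty numeric sequence.
#' @return An object of class `grey_ago`: list with `original`, `ago` and
#'   `background` (length n - 1, aligned to k = 2..n).
#' @examples
#' ago(c(489, 1510, 1501))
#' @export
ago <- function(x) {
  check(is.numeric(x) && length(x) >= 1, "`x` must be a non-empty numeric sequence",
        "empty")
  a <- cumsum(x)
  structure(
    list(
      original = x,
      ago = a,
      background = if (length(x) >= 2) (a[-1] + a[-length(a)]) / 2 else numeric(0)
    ),
    class = "grey_ago"
  )
}

# inverse of the AGO: first differences anchored at the first element
inverse_ago <- function(a) c(a[1], diff(a))

#' Affine matrix-exponential action
#'
#' Evaluates the exact solution of the affine ODE
#' \eqn{\dot x = A x + B}, \eqn{x(0) = v}, at time `t`:
#' \eqn{e^{At}v + \left(\int_0^t e^{As}\,ds\right) B}. Computed through the
#' exponential of the augmented matrix \eqn{\begin{pmatrix}A & B\\ 0 &
#' 0\end{pmatrix}} (scaling-and-squaring), so a singular or ill-conditioned
#' `A` needs no explicit inverse. For invertible `A` this equals
#' \eqn{e^{At}v + A^{-1}(e^{At} - I)B}.
#'
#' @param A Square m x m matrix.
#' @param t Scalar time.
#' @param v Initial state, length m.
#' @param B Constant forcing vector, length m.
#' @return Numeric vector of length m.
#' @examples
#' matrix_exponential_action(matrix(0, 2, 2), t = 2, v = c(1, 1), B = c(3, 4))
#' @export
matrix_exponential_action <- function(A, t, v, B) {
  A <- as.matrix(A)
  m <- nrow(A)
  check(ncol(A) == m && length(v) == m && length(B) == m,
        "dimensions of A, v and B must agree", "dims")
  aug <- rbind(cbind(A, B), 0)
  out <- as.numeric(Matrix::expm(Matrix::Matrix(aug * t)) %*% c(v, 1))
  out[seq_len(m)]
}

#' Fit the single-variable grey model GM(1,1)
#'
#' The classical grey model for one positive series: development coefficient
#' `a` and grey input `b` are estimated by least squares on
#' \eqn{x^{(0)}(k) = -a\,z(k) + b} over k = 2..n, where z is the background
#' sequence of the AGO series; fitted values come from the whitening solution
#' \eqn{\hat x^{(1)}(k) = (x^{(0)}(1) - b/a)\,e^{-a(k-1)} + b/a} differenced
#' back to the original scale, so the first fitted value equals the first
#' observation exactly.
#'
#' @param x A positive numeric sequence (length >= 4), or a [grey_panel()]
#'   whose dependent series is used.
#' @param years Optional year labels (taken from the panel when given one).
#' @return A `grey_gm11` object (inherits `grey_fit`) with components `a`,
#'   `b`, `fitted`, `actual`, `ago_fitted`, `years`, `label`.
#' @examples
#' fit_gm11(michigan_roundabouts())
#' @export
fit_gm11 <- function(x, years = NULL) {
  if (inherits(x, "grey_panel")) {
    years <- panel_years(x)
    x <- x[[panel_dependent(x)]]
  }
  n <- length(x)
  check(n >= 4, sprintf("too few time points (%d); need at least 4", n), "too_short")
  check(all(x > 0), "GM(1,1) requires a strictly positive series",
        "nonpositive_dependent")
  z <- ago(x)$background
  theta <- solve_ls(cbind(-z, 1), x[-1])
  a <- theta[1]
  b <- theta[2]
  check(abs(a) > 1e-12, "degenerate model: development coefficient a is ~0 (constant trend)",
        "degenerate")
  k <- seq_len(n)
  ago_fitted <- (x[1] - b / a) * exp(-a * (k - 1)) + b / a
  structure(
    list(
      label = "GM(1,1)",
      a = a, b = b,
      actual = x,
      fitted = inverse_ago(ago_fitted),
      ago_fitted = ago_fitted,
      years = if (is.null(years)) k else years,
      n = n
    ),
    class = c("grey_gm11", "grey_fit")
  )
}

#' Fit a multivariate grey model MGM(1,n)
#'
#' Models the dependent series jointly with `n` selected factor series
#' (`factors`), all on the AGO scale. Two forms are available:
#'
#' * `coupling = "driven"` (default): the single whitening equation
#'   \eqn{dx_1^{(1)}/dt + a\,x_1^{(1)} = \sum_i b_i x_i^{(1)}} — the
#'   classical GM(1,N) convolution model. Parameters \eqn{(a, b_i)} come from
#'   least squares of \eqn{x_1^{(0)}(k)} on \eqn{(-z_1(k), x_i^{(1)}(k))},
#'   k = 2..n, and fitted values from the standard approximate time-response
#'   \eqn{\hat x_1^{(1)}(k) = [x_1^{(0)}(1) - d(k)/a]\,e^{-a(k-1)} + d(k)/a}
#'   with driver term \eqn{d(k) = \sum_i b_i x_i^{(1)}(k)}. This is the form
#'   whose fitted series reproduces the reference results of the packaged
#'   Michigan worked example.
#' * `coupling = "coupled"`: the full first-order system
#'   \eqn{d\tilde X^{(1)}/dt = A \tilde X^{(1)} + B} over all m = n + 1
#'   series. Each row of \eqn{[A|B]} is estimated by least squares of
#'   \eqn{x_i^{(0)}(k)} on the background values of all series plus a
#'   constant; the solution is evaluated at integer times through the
#'   augmented matrix exponential with the exponent shifted to
#'   \eqn{A\,(t-1)} so the initial condition
#'   \eqn{\tilde X^{(1)}(1) = X^{(1)}(1)} holds exactly.
#'
#' In both forms the first fitted value equals the first observation, and
#' fitted AGO series are differenced back to the original scale. Least
#' squares uses a rank-revealing SVD; a rank-deficient design (easy to hit
#' with many near-collinear factors and few years) yields the minimum-norm
#' solution with a classed warning.
#'
#' @param panel A [grey_panel()].
#' @param factors Character vector of factor ids to include (ordered). When
#'   `NULL`, all panel factors are used.
#' @param coupling `"driven"` or `"coupled"`; see Details.
#' @return A `grey_mgm` object (inherits `grey_fit`). Common components:
#'   `label`, `variable_ids`, `actual`, `fitted`, `years`, `coupling`.
#'   Driven form adds `a` (development coefficient) and `b` (named driver
#'   coefficients); coupled form adds the m x m matrix `A`, vector `B` and
#'   the per-variable `fitted_all` matrix.
#' @examples
#' fit_mgm(michigan_roundabouts(), factors = c("X1", "X2", "X3", "X6"))
#' @export
fit_mgm <- function(panel, factors = NULL,
                    coupling = c("driven", "coupled")) {
  coupling <- match.arg(coupling)
  check(inherits(panel, "grey_panel"), "`panel` must be a grey_panel", "input")
  if (is.null(factors)) factors <- panel_factors(panel)
  missing <- setdiff(factors, panel_factors(panel))
  check(length(missing) == 0,
        sprintf("unknown factor ids: %s", paste(missing, collapse = ", ")),
        "missing_column")
  if (coupling == "driven") {
    check(length(factors) >= 1, "the driven form needs at least one factor",
          "no_factors")
  }

  dep <- panel_dependent(panel)
  ids <- c(dep, factors)
  series <- panel_series(panel)[ids]
  n <- nrow(panel)
  label <- sprintf("MGM(1,%d)", length(factors))

  if (coupling == "driven") {
    x <- series[[dep]]
    agos <- purrr::map(series[factors], ~ ago(.x)$ago)
    z1 <- ago(x)$background
    D <- cbind(-z1, do.call(cbind, purrr::map(agos, ~ .x[-1])))
    theta <- solve_ls(D, x[-1])
    a <- theta[1]
    b <- setNames(theta[-1], factors)
    check(abs(a) > 1e-12,
          "degenerate model: development coefficient a is ~0", "degenerate")
    drive <- as.numeric(do.call(cbind, agos) %*% b)
    k <- seq_len(n)
    ago_fitted <- (x[1] - drive / a) * exp(-a * (k - 1)) + drive / a
    ago_fitted[1] <- x[1]   # response form anchors the initial condition
    fit <- structure(
      list(
        label = label, coupling = coupling, variable_ids = ids,
        a = a, b = b,
        actual = x, fitted = inverse_ago(ago_fitted),
        ago_fitted = ago_fitted,
        years = panel_years(panel), n = n, panel = panel
      ),
      class = c("grey_mgm", "grey_fit")
    )
    return(fit)
  }

  # coupled system: one least-squares problem per variable, common design
  m <- length(ids)
  agos <- purrr::map(series, ~ ago(.x))
  Z <- do.call(cbind, purrr::map(agos, "background"))   # (n-1) x m
  P <- cbind(Z, 1)
  alpha <- purrr::map(series, ~ solve_ls(P, .x[-1]))    # each length m + 1
  A <- do.call(rbind, purrr::map(alpha, ~ .x[seq_len(m)]))
  B <- purrr::map_dbl(alpha, m + 1)
  dimnames(A) <- list(ids, ids)
  names(B) <- ids

  x1 <- purrr::map_dbl(agos, ~ .x$ago[1])
  E <- as.matrix(Matrix::expm(Matrix::Matrix(rbind(cbind(A, B), 0))))
  state <- c(x1, 1)
  ago_fitted <- matrix(NA_real_, n, m, dimnames = list(NULL, ids))
  for (t in seq_len(n)) {            # exponent A (t - 1): exact at t = 1
    ago_fitted[t, ] <- state[seq_len(m)]
    state <- E %*% state
  }
  fitted_all <- apply(ago_fitted, 2, inverse_ago)
  structure(
    list(
      label = label, coupling = coupling, variable_ids = ids,
      A = A, B = B,
      actual = series[[dep]], fitted = fitted_all[, dep],
      fitted_all = fitted_all, ago_fitted = ago_fitted,
      design = P, residuals_ls = purrr::imap(alpha, ~ series[[.y]][-1] - P %*% .x),
      years = panel_years(panel), n = n, panel = panel
    ),
    class = c("grey_mgm", "grey_fit")
  )
}

#' Forecast from a fitted grey model
#'
#' Extends the model's continuous-time solution past the observed window and
#' differences back to the original scale. For the driven MGM form the factor
#' AGO trajectories are themselves extended with per-factor GM(1,1) models
#' (the standard device when future driver values are unknown).
#'
#' @param object A fitted grey model.
#' @param h Forecast horizon (positive integer number of steps).
#' @param ... Unused.
#' @return A tibble with columns `step`, `year` and `forecast` (dependent
#'   series), plus `variable` for the coupled form (all variables).
#' @examples
#' forecast(fit_gm11(michigan_roundabouts()), h = 2)
#' @export
forecast <- function(object, h = 1, ...) UseMethod("forecast")

new_years <- function(years, h) {
  step <- if (length(years) >= 2) diff(years)[1] else 1
  max(years) + step * seq_len(h)
}

#' @rdname forecast
#' @export
forecast.grey_gm11 <- function(object, h = 1, ...) {
  check(is.numeric(h) && h >= 1, "`h` must be a positive integer", "horizon")
  n <- object$n
  k <- n + seq_len(h)
  ago_ext <- (object$actual[1] - object$b / object$a) *
    exp(-object$a * (k - 1)) + object$b / object$a
  fc <- diff(c(object$ago_fitted[n], ago_ext))
  tibble(step = seq_len(h), year = new_years(object$years, h), forecast = fc)
}

#' @rdname forecast
#' @export
forecast.grey_mgm <- function(object, h = 1, ...) {
  check(is.numeric(h) && h >= 1, "`h` must be a positive integer", "horizon")
  n <- object$n
  yrs <- new_years(object$years, h)
  if (object$coupling == "driven") {
    ids <- object$variable_ids[-1]
    # extend each driver's AGO path with its own GM(1,1)
    drive_ext <- purrr::map(ids, function(f) {
      g <- fit_gm11(object$panel[[f]])
      k <- n + seq_len(h)
      (g$actual[1] - g$b / g$a) * exp(-g$a * (k - 1)) + g$b / g$a
    })
    drive <- as.numeric(do.call(cbind, drive_ext) %*% object$b)
    k <- n + seq_len(h)
    ago_ext <- (object$actual[1] - drive / object$a) *
      exp(-object$a * (k - 1)) + drive / object$a
    fc <- diff(c(object$ago_fitted[n], ago_ext))
    return(tibble(step = seq_len(h), year = yrs, forecast = fc))
  }
  m <- length(object$variable_ids)
  E <- as.matrix(Matrix::expm(Matrix::Matrix(rbind(cbind(object$A, object$B), 0))))
  state <- c(object$ago_fitted[n, ], 1)
  prev <- object$ago_fitted[n, ]
  out <- vector("list", h)
  for (s in seq_len(h)) {
    state <- E %*% state
    cur <- state[seq_len(m)]
    out[[s]] <- tibble(
      step = s, year = yrs[s], variable = object$variable_ids,
      forecast = as.numeric(cur - prev)
    )
    prev <- cur
  }
  dplyr::bind_rows(out)
}

#' @export
print.grey_fit <- function(x, ...) {
  cat(sprintf("%s fit over %d points (%s-%s)\n", x$label, x$n,
              min(x$years), max(x$years)))
  if (!is.null(x$a)) cat(sprintf("  development coefficient a = %.6g\n", x$a))
  if (!is.null(x$b) && length(x$b) == 1 && is.null(names(x$b))) {
    cat(sprintf("  grey input b = %.6g\n", x$b))
  }
  print(tidy(x), n = 6)
  invisible(x)
}

#' Tidy a fitted grey model
#'
#' @param x A `grey_fit` object.
#' @param ... Unused.
#' @return One row per time point: `year`, `actual`, `fitted` and the
#'   relative `residual` (actual-value denominator, unrounded).
#' @export
tidy.grey_fit <- function(x, ...) {
  tibble(
    year = x$years, actual = x$actual, fitted = x$fitted,
    residual = (x$actual - x$fitted) / x$actual
  )
}

#' Summarize a fitted grey model
#'
#' @param x A `grey_fit` object.
#' @param round_fitted Apply the integer reporting convention before the
#'   error metrics (default `TRUE`; see [grey_config()]).
#' @param ... Unused.
#' @return A one-row tibble: `label`, `n`, `mape`, `mae`, `rmse`.
#' @export
glance.grey_fit <- function(x, round_fitted = TRUE, ...) {
  f <- if (round_fitted) round_half_up(x$fitted) else x$fitted
  tibble(
    label = x$label, n = x$n,
    mape = mape(x$actual, f), mae = mae(x$actual, f), rmse = rmse(x$actual, f)
  )
}

#' @rdname tidy.grey_fit
#' @param object A `grey_fit` object.
#' @export
autoplot.grey_fit <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("actual", "fitted"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "year", y = "count", colour = NULL,
                  title = object$label) +
    ggplot2::theme_minimal()
}
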