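#' Random stable system matrix
#'
#' Draws an m x m matrix and rescales it to a target spectral radius. Kept
#' small (default 0.3) so that sampling the continuous system at integer
#' times stays well-conditioned and the adjacent-mean background is a good
#' integral approximation.
#'
#' @param m Dimension.
#' @param spectral_radius Target spectral radius (<= 0.5 recommended).
#' @return An m x m matrix.
#' @export
random_system_matrix <- function(m, spectral_radius = 0.3) {
  A <- matrix(rnorm(m * m), m, m)
  r <- max(Mod(eigen(A, only.values = TRUE)$values))
  A * (spectral_radius / r)
}

# multiplicative lognormal noise with mean 1 and coefficient of variation cv
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a panel from a known affine linear system
#'
#' Integrates \eqn{dX^{(1)}/dt = A X^{(1)} + B} exactly at integer times
#' from a positive initial AGO state, differences back to the original
#' scale, and applies multiplicative lognormal noise with coefficient of
#' variation `noise_cv`. Variable 1 is the dependent series. The true
#' `(A, B)` are returned, making the generator its own oracle for
#' parameter-recovery and forecast tests. Draws whose original-scale values
#' are not strictly positive are rejected and redrawn (bounded retries).
#'
#' @param m Number of variables (dependent + m - 1 factors).
#' @param n Series length (4-16).
#' @param A,B Optional true system; drawn via [random_system_matrix()] and
#'   `runif` when `NULL`.
#' @param x0 Optional positive initial AGO state.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives the exact system trajectory).
#' @param seed Integer seed (required for reproducibility).
#' @param start_year First calendar year label.
#' @return A list: `panel` (a [grey_panel()] with dependent `y` and factors
#'   `X1`...), `A`, `B`, `x0`, and `ago` (the exact AGO trajectory, n x m).
#' @examples
#' gen_linear_system_panel(m = 3, n = 8, seed = 1)$panel
#' @export
gen_linear_system_panel <- function(m = 3, n = 8, A = NULL, B = NULL,
                                    x0 = NULL, noise_cv = 0, seed = NULL,
                                    start_year = 2001) {
  check(n >= 4 && n <= 16, "`n` must be in 4..16", "config")
  check(noise_cv >= 0, "`noise_cv` must be >= 0", "config")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in 1:20) {
    Ai <- if (is.null(A)) random_system_matrix(m) else A
    Bi <- if (is.null(B)) runif(m, 5, 20) else B
    x0i <- if (is.null(x0)) runif(m, 20, 100) else x0
    check(all(x0i > 0), "`x0` must be strictly positive", "config")
    if (!is.null(A)) {
      r <- max(Mod(eigen(Ai, only.values = TRUE)$values))
      check(r <= 0.5 + 1e-12, "`A` must have spectral radius <= 0.5", "config")
    }
    traj <- t(sapply(seq_len(n), function(t) {
      matrix_exponential_action(Ai, t - 1, x0i, Bi)
    }))
    orig <- apply(traj, 2, inverse_ago)
    noisy <- orig * matrix(lognoise(n * m, noise_cv), n, m)
    if (all(noisy > 0)) {
      ids <- c("y", paste0("X", seq_len(m - 1)))
      colnames(noisy) <- ids
      df <- as_tibble(as.data.frame(noisy))
      df$year <- start_year + seq_len(n) - 1
      return(list(
        panel = grey_panel(df, dependent = "y"),
        A = Ai, B = Bi, x0 = x0i, ago = traj
      ))
    }
    if (attempt == 1) {
      warn("non-positive generated value; redrawing",
           class = "greycast_warn_redraw")
    }
    if (!is.null(A) && !is.null(B) && !is.null(x0) && noise_cv == 0) {
      abort("the specified noise-free system produces non-positive values",
            class = "greycast_error_nonpositive_draw")
    }
  }
  abort("failed to generate a strictly positive panel in 20 attempts",
        class = "greycast_error_nonpositive_draw")
}

#' Generate a series from a known GM(1,1) law
#'
#' Evaluates the GM(1,1) whitening solution
#' \eqn{\hat x^{(1)}(k) = (x_1 - b/a)e^{-a(k-1)} + b/a}, differences it and
#' applies multiplicative lognormal noise. Refitting the noise-free output
#' with [fit_gm11()] recovers `(a, b)` up to the small adjacent-mean
#' background bias.
#'
#' @param a Development coefficient (nonzero; negative means growth).
#' @param b Grey input.
#' @param x1 First (positive) value of the series.
#' @param n Series length (>= 4).
#' @param noise_cv Coefficient of variation of the noise.
#' @param seed Integer seed.
#' @return A list: `series`, `a`, `b`, `x1`.
#' @examples
#' gen_gm11_series(a = -0.1, b = 100, x1 = 50, n = 8)$series
#' @export
gen_gm11_series <- function(a, b, x1, n, noise_cv = 0, seed = NULL) {
  check(abs(a) > 1e-12, "`a` = 0 is degenerate (no grey dynamics)", "degenerate")
  check(n >= 4, "`n` must be >= 4", "config")
  check(x1 > 0, "`x1` must be positive", "config")
  if (!is.null(seed)) set.seed(seed)
  k <- seq_len(n)
  agov <- (x1 - b / a) * exp(-a * (k - 1)) + b / a
  x <- inverse_ago(agov) * lognoise(n, noise_cv)
  check(all(x > 0), "generated series is not strictly positive",
        "nonpositive_draw")
  list(series = x, a = a, b = b, x1 = x1)
}

#' Generate a crash-like multivariate count panel
#'
#' A seeded panel mimicking the magnitude regime of short annual road-crash
#' tables: 6-10 years, a dependent series in the hundreds to thousands with
#' near-exponential trend and strong multiplicative fluctuation, and 6-8
#' factor series spanning units to hundreds. Intended for end-to-end smoke
#' tests of the pipeline; it carries no mechanistic crash model.
#'
#' @param seed Integer seed.
#' @return A [grey_panel()] with dependent `total`.
#' @examples
#' gen_crashlike_panel(seed = 42)
#' @export
gen_crashlike_panel <- function(seed = 1) {
  set.seed(seed)
  n <- sample(6:10, 1)
  n_factors <- sample(6:8, 1)
  growth <- runif(1, 0.05, 0.2)
  base <- runif(1, 400, 900)
  total <- pmax(round(base * exp(growth * (seq_len(n) - 1)) *
                        lognoise(n, 0.15)), 50)
  scales <- runif(n_factors, 0.005, 0.4)
  factors <- purrr::map(scales, function(s) {
    pmax(round(total * s * lognoise(n, 0.2)), 1)
  })
  names(factors) <- paste0("X", seq_len(n_factors))
  df <- tibble(year = 2015 + seq_len(n), total = as.numeric(total))
  for (f in names(factors)) df[[f]] <- as.numeric(factors[[f]])
  grey_panel(df, dependent = "total")
}
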