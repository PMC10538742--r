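test_that("accumulated generation and its inverse are exact", {
  a <- ago(c(489, 1510, 1501))
  expect_equal(a$ago, c(489, 1999, 3500))
  expect_equal(a$background, c(1244, 2749.5))

  a <- ago(c(1, 1, 1, 1))
  expect_equal(a$ago, 1:4)
  expect_equal(a$background, c(1.5, 2.5, 3.5))

  single <- ago(5)
  expect_equal(single$ago, 5)
  expect_length(single$background, 0)
  expect_error(ago(numeric(0)), class = "greycast_error_empty")

  # AGO / difference round-trip is bit-exact for integer inputs
  for (seed in 1:5) {
    set.seed(seed)
    x <- as.numeric(sample(1:5000, 12, replace = TRUE))
    expect_identical(greycast:::inverse_ago(ago(x)$ago), x)
  }
})

test_that("matrix_exponential_action solves the affine ODE", {
  # A = 0: pure drift v + tB
  expect_equal(matrix_exponential_action(matrix(0, 2, 2), 2, c(1, 1), c(3, 4)),
               c(7, 9))
  # scalar decay, no forcing
  expect_equal(matrix_exponential_action(matrix(-1, 1, 1), 1, 1, 0),
               exp(-1), tolerance = 1e-12)
  # invertible A: matches the closed form e^{At} v + A^-1 (e^{At} - I) B
  set.seed(4)
  A <- matrix(rnorm(9, sd = 0.4), 3, 3)
  B <- runif(3); v <- runif(3); t <- 1.7
  E <- as.matrix(Matrix::expm(A * t))
  closed <- as.numeric(E %*% v + solve(A) %*% (E - diag(3)) %*% B)
  expect_equal(matrix_exponential_action(A, t, v, B), closed, tolerance = 1e-10)
})

test_that("matrix_exponential_action agrees with a numerical ODE integrator", {
  skip_if_not_installed("deSolve")
  set.seed(8)
  A <- matrix(rnorm(9, sd = 0.3), 3, 3)
  B <- runif(3); v <- runif(3, 1, 2)
  sol <- deSolve::ode(
    y = v, times = c(0, 1, 2.5),
    func = function(t, y, parms) list(A %*% y + B),
    parms = NULL, method = "lsoda", rtol = 1e-12, atol = 1e-12
  )
  for (i in 2:3) {
    expect_equal(matrix_exponential_action(A, sol[i, "time"], v, B),
                 unname(sol[i, -1]), tolerance = 1e-8)
  }
})

test_that("GM(1,1) recovers known grey dynamics and anchors its first point", {
  g <- gen_gm11_series(a = -0.1, b = 100, x1 = 50, n = 8)
  f <- fit_gm11(g$series)
  expect_lt(abs(f$a - (-0.1)) / 0.1, 0.05)
  expect_lt(abs(f$b - 100) / 100, 0.05)
  expect_equal(f$fitted[1], g$series[1])

  expect_error(fit_gm11(c(1, 2, 3)), class = "greycast_error_too_short")
  expect_error(fit_gm11(c(1, -2, 3, 4)),
               class = "greycast_error_nonpositive_dependent")
  # constant series: a ~ 0 is degenerate
  expect_error(fit_gm11(rep(10, 6)), class = "greycast_error_degenerate")
})

test_that("every grey fit reproduces its first observation exactly", {
  p <- michigan_roundabouts()
  expect_equal(fit_gm11(p)$fitted[1], 489)
  expect_equal(fit_mgm(p, c("X1", "X2", "X3", "X6"))$fitted[1], 489)
  cp <- suppressWarnings(fit_mgm(p, c("X3", "X6"), coupling = "coupled"))
  expect_equal(unname(cp$fitted_all[1, ]), c(489, 146, 5))
  for (seed in c(1, 6)) {
    sim <- suppressWarnings(gen_linear_system_panel(m = 3, n = 8, seed = seed))
    fit <- suppressWarnings(fit_mgm(sim$panel, coupling = "coupled"))
    expect_equal(unname(fit$fitted_all[1, ]),
                 unname(as.matrix(sim$panel[1, fit$variable_ids]))[1, ])
  }
})

test_that("the coupled model with no factors collapses to GM(1,1)", {
  p <- michigan_roundabouts()
  gm <- fit_gm11(p)
  mgm1 <- fit_mgm(p, factors = character(0), coupling = "coupled")
  expect_equal(unname(mgm1$A[1, 1]), -gm$a, tolerance = 1e-9)
  expect_equal(unname(mgm1$B[1]), gm$b, tolerance = 1e-9)
  expect_equal(unname(mgm1$fitted), gm$fitted, tolerance = 1e-9)
})

test_that("coupled least squares leaves residuals orthogonal to the design", {
  sim <- suppressWarnings(gen_linear_system_panel(m = 3, n = 10, noise_cv = 0.2,
                                                  seed = 13))
  fit <- suppressWarnings(fit_mgm(sim$panel, coupling = "coupled"))
  for (r in fit$residuals_ls) {
    g <- crossprod(fit$design, r)
    expect_lt(max(abs(g)) / max(abs(fit$design)), 1e-6)
  }
})

test_that("noise-free linear systems are recovered within tolerance", {
  # 20 seeded replicates; elementwise 5% on well-scaled entries, 5% overall
  for (seed in 1:20) {
    sim <- suppressWarnings(gen_linear_system_panel(m = 3, n = 8, seed = seed))
    fit <- suppressWarnings(fit_mgm(sim$panel, coupling = "coupled"))
    big <- abs(sim$A) >= 0.1 * max(abs(sim$A))
    expect_lt(max(abs(fit$A - sim$A)[big] / abs(sim$A)[big]), 0.05)
    expect_lt(norm(fit$A - sim$A, "F") / norm(sim$A, "F"), 0.05)
    expect_lt(max(abs(fit$B - sim$B) / abs(sim$B)), 0.05)
  }
})

test_that("forecasts continue the fitted continuous solution", {
  sim <- suppressWarnings(gen_linear_system_panel(m = 3, n = 8, seed = 3))
  fit <- suppressWarnings(fit_mgm(sim$panel, coupling = "coupled"))
  n <- fit$n
  # regenerating from the *fitted* system must reproduce fit + forecasts
  sim2 <- gen_linear_system_panel(m = 3, n = n + 2, A = fit$A, B = fit$B,
                                  x0 = fit$ago_fitted[1, ], noise_cv = 0)
  dep2 <- sim2$panel[[panel_dependent(sim2$panel)]]
  expect_equal(dep2[seq_len(n)], unname(fit$fitted), tolerance = 1e-8)
  fc <- forecast(fit, h = 2)
  got <- fc$forecast[fc$variable == fit$variable_ids[1]]
  expect_equal(got, dep2[n + 1:2], tolerance = 1e-6)

  expect_error(forecast(fit, h = 0), class = "greycast_error_horizon")
})

test_that("GM(1,1) forecasting extends the whitening solution", {
  g <- gen_gm11_series(a = -0.08, b = 60, x1 = 40, n = 10)
  f <- fit_gm11(g$series[1:7])
  fc <- forecast(f, h = 3)
  # refit on a noise-free grey law: continuation matches the law closely
  expect_equal(fc$forecast, g$series[8:10], tolerance = 0.01)
})

test_that("driven MGM fits are invariant to factor ordering and deterministic", {
  p <- michigan_roundabouts()
  f1 <- fit_mgm(p, c("X1", "X2", "X3", "X6"))
  f2 <- fit_mgm(p, c("X6", "X3", "X2", "X1"))
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-9)
  f3 <- fit_mgm(p, c("X1", "X2", "X3", "X6"))
  expect_identical(f1$fitted, f3$fitted)
  expect_error(fit_mgm(p, character(0)), class = "greycast_error_no_factors")
  expect_error(fit_mgm(p, c("X1", "nope")), class = "greycast_error_missing_column")
})

test_that("tidy/glance/autoplot summarize a fit", {
  fit <- fit_mgm(michigan_roundabouts(), c("X1", "X2", "X3", "X6"))
  td <- tidy(fit)
  expect_equal(td$year, 2016:2021)
  expect_equal(td$residual, (td$actual - td$fitted) / td$actual)
  gl <- glance(fit)
  expect_equal(gl$label, "MGM(1,4)")
  expect_true(all(c("mape", "mae", "rmse") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
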