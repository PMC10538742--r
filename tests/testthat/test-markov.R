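test_that("relative residuals follow the chosen denominator convention", {
  expect_equal(round(relative_residuals(1510, 1308), 4), 0.1338)
  expect_equal(round(relative_residuals(1501, 1653), 4), -0.1013)
  expect_equal(relative_residuals(100, 100), 0)
  expect_equal(relative_residuals(100, 100, "fitted"), 0)
  expect_equal(relative_residuals(120, 100, "fitted"), 0.2)
  expect_equal(relative_residuals(120, 100, "actual"), 1 / 6)
  expect_error(relative_residuals(c(1, 0), c(1, 1)),
               class = "greycast_error_zero_divisor")
  expect_error(relative_residuals(1:3, 1:2), class = "greycast_error_length")
})

test_that("equal-width state partitions span the residual range", {
  b <- partition_states(c(0, 0.1, 0.3, 0.25), s = 3)
  expect_equal(attr(b, "edges"), c(0, 0.1, 0.2, 0.3))
  expect_equal(b$midpoint, c(0.05, 0.15, 0.25))

  b2 <- partition_states(c(-1, 1), s = 2)
  expect_equal(attr(b2, "edges"), c(-1, 0, 1))
  expect_true(all(diff(diff(attr(b2, "edges"))) == 0))

  expect_error(partition_states(rep(0.02, 5), s = 3),
               class = "greycast_error_zero_width")
})

test_that("state assignment uses half-open intervals with a closed top", {
  res <- c(0, 0.1338, -0.1013, -0.0247, -0.0062, -0.0023)
  b <- partition_states(res, 3)
  st <- assign_states(res, b)
  expect_equal(st, c(2, 3, 1, 1, 2, 2))
  # interior boundary belongs to the upper interval; the maximum is assigned
  lower_edge_of_s2 <- attr(b, "edges")[2]
  expect_equal(assign_states(lower_edge_of_s2, b), 2)
  expect_equal(assign_states(max(res), b), 3)
  expect_error(assign_states(1e3, b), class = "greycast_error_out_of_bounds")
})

test_that("transition estimation counts adjacent pairs and normalizes rows", {
  tr <- estimate_transitions(c(2, 3, 1, 1, 2, 2), s = 3)
  expect_equal(tr$P1,
               matrix(c(1/2, 1/2, 0, 0, 1/2, 1/2, 1, 0, 0), 3, byrow = TRUE))
  expect_equal(tr$source, c(2, 2, 1))
  expect_equal(rowSums(tr$counts), tr$source)

  expect_warning(tr1 <- estimate_transitions(c(1, 1, 1), s = 3),
                 class = "greycast_warn_unvisited")
  expect_equal(tr1$P1[1, ], c(1, 0, 0))
  expect_equal(tr1$P1[2, ], rep(1/3, 3))     # unvisited row made uniform

  tr2 <- estimate_transitions(c(1, 2, 1, 2), s = 2)
  expect_equal(tr2$P1, matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
})

test_that("k-step matrices obey Chapman-Kolmogorov and match path enumeration", {
  tr <- estimate_transitions(c(2, 3, 1, 1, 2, 2), s = 3)
  P1 <- tr$P1
  expect_equal(kstep(P1, 1), P1)
  for (k in 1:4) {
    Pk <- kstep(P1, k)
    expect_equal(rowSums(Pk), rep(1, 3), tolerance = 1e-12)
    expect_equal(Pk, oracle_kstep(P1, k), tolerance = 1e-12)
  }
  # semigroup property on a second, denser chain
  set.seed(21)
  st <- sample(1:3, 15, replace = TRUE)
  P <- suppressWarnings(estimate_transitions(st, 3)$P1)
  expect_equal(kstep(P, 5), kstep(P, 2) %*% kstep(P, 3), tolerance = 1e-12)
  expect_equal(kstep(P, 3), oracle_kstep(P, 3), tolerance = 1e-12)
  expect_error(kstep(P, 0), class = "greycast_error_horizon")
})

test_that("future state voting sums k-step rows over the recent history", {
  st <- c(2, 3, 1, 1, 2, 2)
  P1 <- estimate_transitions(st, 3)$P1
  fut <- future_state_distribution(st, P1, lookback = 3)
  expect_equal(fut$weights, c(7/8, 9/8, 1))
  expect_equal(fut$modal, 2)
  # lookback 1 from terminal state S2: tie between S2 and S3, lower index wins
  expect_warning(f1 <- future_state_distribution(st, P1, lookback = 1),
                 class = "greycast_warn_tie")
  expect_equal(f1$weights, c(0, 1/2, 1/2))
  expect_equal(f1$modal, 2)
  # deterministic chain: all weight stays on the terminal state
  fid <- future_state_distribution(c(2, 2, 2), diag(3), lookback = 2)
  expect_equal(fid$modal, 2)
  expect_error(future_state_distribution(st, P1, lookback = 99),
               class = "greycast_error_length")
})

test_that("midpoint correction rescales fitted values by their state", {
  b <- partition_states(c(-0.1, 0.1), s = 2)   # midpoints -0.05, +0.05
  expect_equal(correct_fitted(c(100, 200), c(1, 2), b), c(95, 210))
  b0 <- partition_states(c(-0.2, 0.2), s = 2)
  expect_equal(correct_fitted(1000, 2, b0), 1100)
  expect_equal(forecast_corrected(1000, tibble::tibble(midpoint = 0.15)), 1150)
  # a state symmetric about zero leaves the value unchanged
  b1 <- partition_states(c(-0.3, 0.3), s = 3)
  expect_equal(correct_fitted(123, 2, b1), 123)
})

test_that("midpoint-exact residuals are corrected back to the actual values", {
  # under the fitted-value denominator the correction is algebraically exact
  # when each residual sits at its state midpoint
  b <- partition_states(c(-0.12, 0.12, 0.01, -0.05), s = 3)
  expect_equal(b$midpoint, c(-0.08, 0, 0.08))
  fitted <- c(100, 200, 150, 300, 220)
  st_true <- c(1, 2, 2, 1, 3)
  actual <- fitted * (1 + b$midpoint[st_true])
  res <- relative_residuals(actual, fitted, denominator = "fitted")
  st <- assign_states(res, b)
  expect_equal(st, st_true)
  expect_equal(correct_fitted(fitted, st, b), actual, tolerance = 1e-12)
  # under the actual-value denominator recovery holds to first order in the
  # residual (error of order midpoint^2)
  res_a <- relative_residuals(actual, fitted, denominator = "actual")
  st_a <- assign_states(res_a, b)
  expect_equal(correct_fitted(fitted, st_a, b), actual, tolerance = 0.01)
})

test_that("the full Markov correction improves the Michigan fit", {
  fit <- fit_mgm(michigan_roundabouts(), c("X1", "X2", "X3", "X6"))
  mk <- markov_correct(fit)
  uncorrected <- mape(fit$actual, round_half_up(fit$fitted))
  corrected <- mape(fit$actual, mk$corrected)
  expect_lt(corrected, uncorrected)
  expect_equal(mk$states, c(2, 3, 1, 1, 2, 2))
  expect_equal(mk$future$modal, 2)
  td <- tidy(mk)
  expect_equal(td$corrected, mk$corrected)
  gl <- glance(mk)
  expect_equal(gl$label, "MGM(1,4)-Markov")
  expect_s3_class(autoplot(mk), "ggplot")
})

test_that("the model_forecast base uses the grey model's own projection", {
  fit <- fit_mgm(michigan_roundabouts(), c("X1", "X2", "X3", "X6"))
  mk <- markov_correct(fit, forecast_base = "model_forecast")
  fc1 <- forecast(fit, h = 1)$forecast[1]
  expect_equal(mk$forecast_basis, fc1)
  expect_equal(mk$forecast,
               fc1 * (1 + mk$bounds$midpoint[mk$future$modal]))
})
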