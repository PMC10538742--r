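# Independent oracles: deliberately plain-loop implementations, kept free of
# any code path they are used to check.

# relational grades by direct looping over the definition
oracle_gra_grades <- function(panel, rho = 0.5, normalization = "initial") {
  dep <- panel_dependent(panel)
  ids <- c(dep, panel_factors(panel))
  n <- nrow(panel)
  norm <- list()
  for (id in ids) {
    v <- panel[[id]]
    d <- if (normalization == "initial") v[1] else mean(v)
    norm[[id]] <- v / d
  }
  dmin <- Inf; dmax <- -Inf
  for (f in panel_factors(panel)) {
    for (k in seq_len(n)) {
      d <- abs(norm[[dep]][k] - norm[[f]][k])
      if (d < dmin) dmin <- d
      if (d > dmax) dmax <- d
    }
  }
  grades <- numeric(0)
  for (f in panel_factors(panel)) {
    acc <- 0
    for (k in seq_len(n)) {
      d <- abs(norm[[dep]][k] - norm[[f]][k])
      acc <- acc + (dmin + rho * dmax) / (d + rho * dmax)
    }
    grades[f] <- acc / n
  }
  grades
}

# k-step transition probabilities by enumerating every length-k state path
oracle_kstep <- function(P1, k) {
  s <- nrow(P1)
  out <- matrix(0, s, s)
  paths <- expand.grid(rep(list(seq_len(s)), k + 1))
  for (r in seq_len(nrow(paths))) {
    path <- as.integer(paths[r, ])
    pr <- 1
    for (j in seq_len(k)) pr <- pr * P1[path[j], path[j + 1]]
    out[path[1], path[k + 1]] <- out[path[1], path[k + 1]] + pr
  }
  out
}

oracle_mape <- function(a, p) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs((a[i] - p[i]) / a[i])
  acc / length(a) * 100
}
oracle_mae <- function(a, p) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - p[i])
  acc / length(a)
}
oracle_rmse <- function(a, p) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - p[i])^2
  sqrt(acc / length(a))
}

# random valid panel for round-trip and invariance properties
random_panel <- function(seed, n = NULL, n_factors = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(4:12, 1)
  if (is.null(n_factors)) n_factors <- sample(1:6, 1)
  df <- tibble::tibble(
    year = 2000 + seq_len(n),
    y = round(exp(runif(n, 3, 8)) * exp(rnorm(n, 0, 0.2)), 4)
  )
  for (j in seq_len(n_factors)) {
    df[[paste0("f", j)]] <- round(exp(runif(n, 0, 6)) * exp(rnorm(n, 0, 0.3)), 4)
  }
  grey_panel(df, dependent = "y")
}
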