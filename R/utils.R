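# internal helpers shared across modules

#' Round half away from zero
#'
#' Base [round()] rounds half to even; published count tables round half away
#' from zero, so fitted crash counts use this convention when displayed or
#' when the analysis is run at reporting precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5, 2.345), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# least squares via SVD pseudoinverse: rank-revealing, returns minimum-norm
# solution when the system is rank deficient (short panels make this common)
solve_ls <- function(X, y, warn_rank = TRUE) {
  s <- svd(X)
  tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) {
    abort("design matrix is numerically zero", class = "greycast_error_rank")
  }
  if (warn_rank && sum(pos) < ncol(X)) {
    warn(
      sprintf(
        "design matrix is rank deficient (rank %d of %d columns); using the minimum-norm least-squares solution",
        sum(pos), ncol(X)
      ),
      class = "greycast_warn_rank"
    )
  }
  drop(s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * crossprod(s$u[, pos, drop = FALSE], y)))
}

# stop unless `ok`, with a classed condition so callers can test failures
check <- function(ok, msg, class) {
  if (!isTRUE(ok)) abort(msg, class = paste0("greycast_error_", class))
  invisible(TRUE)
}
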