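#' Normalize panel series to a dimensionless scale
#'
#' Grey relational analysis compares the geometric shapes of sequence curves,
#' so raw counts of very different magnitudes must first be made
#' dimensionless. Two standard transforms are offered: `"initial"` divides
#' each series by its first element (every curve starts at 1) and `"mean"`
#' divides by the series mean (every curve averages 1). The package default
#' is the initial-value transform; under it the packaged Michigan worked
#' example reproduces its reference relational grades.
#'
#' @param panel A [grey_panel()].
#' @param method `"initial"` or `"mean"`.
#' @return A tibble of the same shape as `panel` with normalized values.
#' @export
normalize_series <- function(panel, method = c("initial", "mean")) {
  method <- match.arg(method)
  out <- as_tibble(panel)
  for (cl in setdiff(names(out), "year")) {
    d <- if (method == "initial") out[[cl]][1] else mean(out[[cl]])
    check(is.finite(d) && d != 0,
          sprintf("cannot normalize series '%s': zero %s value", cl,
                  if (method == "initial") "first" else "mean"),
          "zero_divisor")
    out[[cl]] <- out[[cl]] / d
  }
  out
}

#' Deng relational coefficients for one comparison series
#'
#' The pointwise relational coefficient between a reference curve and a
#' comparison curve is
#' \deqn{\zeta(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                      {|x_1(k) - x_i(k)| + \rho\,\Delta_{max}}}
#' where \eqn{\Delta_{min}}, \eqn{\Delta_{max}} are the two-level minimum and
#' maximum absolute discrepancies taken over *all* comparison series and all
#' time points jointly, and \eqn{\rho \in [0,1]} is the distinguishing
#' coefficient. When every series is identical (\eqn{\Delta_{max} = 0}) all
#' coefficients are 1 by convention.
#'
#' @param reference,comparison Normalized numeric sequences of equal length.
#' @param delta_min,delta_max The global two-level minimum and maximum
#'   discrepancies.
#' @param rho Distinguishing coefficient in \[0, 1\].
#' @return Numeric vector of coefficients in (0, 1\].
#' @export
relational_coefficients <- function(reference, comparison, delta_min,
                                    delta_max, rho = 0.5) {
  check(length(reference) == length(comparison),
        "sequences must have equal length", "length")
  check(rho >= 0 && rho <= 1, "`rho` must be in [0, 1]", "config")
  d <- abs(reference - comparison)
  if (delta_max == 0) return(rep(1, length(d)))
  (delta_min + rho * delta_max) / (d + rho * delta_max)
}

#' Grey relational analysis of a panel
#'
#' Normalizes every series, computes the Deng relational coefficient sequence
#' of each factor against the dependent series (with the two-level min/max
#' discrepancies pooled over all factors), averages them into relational
#' grades, ranks the factors by grade, and screens out factors whose grade
#' falls below `threshold`.
#'
#' @param panel A [grey_panel()].
#' @param rho Distinguishing coefficient (default 0.5).
#' @param threshold Screening threshold on the grade (default 0.7).
#' @param normalization `"initial"` (default) or `"mean"`; see
#'   [normalize_series()].
#' @return A `grey_gra` object with components `grades` (named vector),
#'   `coefficients` (tibble: factor, year, zeta), `ranking`, `kept`,
#'   `delta_min`, `delta_max`, `rho`, `threshold`, `normalization`.
#' @examples
#' gra <- grey_relate(michigan_roundabouts())
#' tidy(gra)
#' @export
grey_relate <- function(panel, rho = 0.5, threshold = 0.7,
                        normalization = c("initial", "mean")) {
  normalization <- match.arg(normalization)
  norm <- normalize_series(panel, normalization)
  dep <- panel_dependent(panel)
  factors <- panel_factors(panel)
  check(length(factors) >= 1, "panel has no factor series", "no_factors")

  ref <- norm[[dep]]
  diffs <- purrr::map(setNames(factors, factors), ~ abs(ref - norm[[.x]]))
  delta_min <- min(purrr::map_dbl(diffs, min))
  delta_max <- max(purrr::map_dbl(diffs, max))

  zetas <- purrr::map(setNames(factors, factors), function(f) {
    relational_coefficients(ref, norm[[f]], delta_min, delta_max, rho)
  })
  grades <- purrr::map_dbl(zetas, mean)

  # descending grade; ties resolved by original column order (stable sort)
  ranking <- factors[order(-grades[factors])]
  kept <- ranking[grades[ranking] >= threshold]

  structure(
    list(
      grades = grades,
      coefficients = purrr::imap_dfr(
        zetas,
        ~ tibble(factor = .y, year = panel_years(panel), zeta = .x)
      ),
      ranking = ranking,
      kept = kept,
      delta_min = delta_min,
      delta_max = delta_max,
      rho = rho,
      threshold = threshold,
      normalization = normalization,
      labels = attr(panel, "labels")
    ),
    class = "grey_gra"
  )
}

#' @export
print.grey_gra <- function(x, ...) {
  cat(sprintf("Grey relational analysis (rho = %g, %s normalization)\n",
              x$rho, x$normalization))
  g <- x$grades[x$ranking]
  for (i in seq_along(g)) {
    cat(sprintf("  %d. %-4s %.4f%s\n", i, names(g)[i], g[i],
                if (names(g)[i] %in% x$kept) "" else "  (screened out)"))
  }
  cat(sprintf("kept %d of %d factors (threshold %g)\n",
              length(x$kept), length(x$ranking), x$threshold))
  invisible(x)
}

#' @describeIn grey_relate One row per factor: grade, rank, kept flag.
#' @param x A `grey_gra` object.
#' @param ... Unused.
#' @export
tidy.grey_gra <- function(x, ...) {
  tibble(
    factor = x$ranking,
    label = if (is.null(x$labels)) NA_character_ else
      unname(x$labels[x$ranking]),
    grade = unname(x$grades[x$ranking]),
    rank = seq_along(x$ranking),
    kept = x$ranking %in% x$kept
  )
}

#' @describeIn grey_relate One-row summary of the screening.
#' @export
glance.grey_gra <- function(x, ...) {
  tibble(
    rho = x$rho, threshold = x$threshold, normalization = x$normalization,
    n_factors = length(x$ranking), n_kept = length(x$kept),
    delta_min = x$delta_min, delta_max = x$delta_max
  )
}

#' @describeIn grey_relate Bar chart of relational grades with the screening
#'   threshold.
#' @param object A `grey_gra` object.
#' @export
autoplot.grey_gra <- function(object, ...) {
  d <- tidy(object)
  d$factor <- factor(d$factor, levels = rev(d$factor))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$factor, y = .data$grade,
                                  fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "grey relational grade", fill = "kept") +
    ggplot2::theme_minimal()
}
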