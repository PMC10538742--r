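#' Construct a validated series panel
#'
#' A series panel is the input object for every analysis in greycast: a wide
#' table with one row per (annual) time point, a `year` column, one strictly
#' positive dependent count series, and any number of non-negative factor
#' series. Grey models need at least four time points; years must be evenly
#' spaced and strictly increasing. Values are kept as doubles throughout —
#' fitted counts are fractional and rounding is a reporting decision, not a
#' storage one.
#'
#' @param data A data frame with a year column and numeric series columns.
#' @param dependent Name of the dependent (response) column.
#' @param year Name of the year column (default `"year"`).
#' @param labels Optional named character vector mapping factor ids to
#'   human-readable descriptions.
#' @return A `grey_panel`: a tibble with attributes `dependent`, `factors`
#'   and `labels`. Rows are sorted by year.
#' @examples
#' grey_panel(data.frame(year = 2001:2005, y = c(5, 7, 8, 11, 12),
#'                       f1 = c(1, 2, 2, 3, 3)), dependent = "y")
#' @seealso [michigan_roundabouts()], [read_panel()]
#' @export
grey_panel <- function(data, dependent, year = "year", labels = NULL) {
  check(is.data.frame(data), "`data` must be a data frame", "input")
  check(year %in% names(data),
        sprintf("year column '%s' not found", year), "missing_column")
  check(dependent %in% names(data),
        sprintf("dependent column '%s' not found", dependent), "missing_column")

  data <- as_tibble(data)
  if (year != "year") data <- dplyr::rename(data, year = dplyr::all_of(year))
  value_cols <- setdiff(names(data), "year")
  factors <- setdiff(value_cols, dependent)

  for (cl in c("year", value_cols)) {
    check(is.numeric(data[[cl]]),
          sprintf("column '%s' is not numeric", cl), "non_numeric")
    check(!anyNA(data[[cl]]),
          sprintf("column '%s' has missing entries", cl), "missing_values")
  }

  data <- dplyr::arrange(data, .data$year)
  n <- nrow(data)
  check(n >= 4, sprintf("too few time points (%d); grey models need at least 4", n),
        "too_short")
  steps <- diff(data$year)
  check(length(unique(steps)) == 1 && steps[1] > 0,
        "years must be strictly increasing with a constant step", "years")
  check(all(data[[dependent]] > 0),
        sprintf("dependent series '%s' must be strictly positive", dependent),
        "nonpositive_dependent")
  for (f in factors) {
    check(all(data[[f]] >= 0),
          sprintf("factor series '%s' has negative values", f), "negative_factor")
  }

  data <- dplyr::relocate(data, "year", dplyr::all_of(dependent))
  structure(
    data,
    dependent = dependent,
    factors = factors,
    labels = labels,
    class = c("grey_panel", class(as_tibble(data)))
  )
}

#' @export
print.grey_panel <- function(x, ...) {
  cat(sprintf(
    "<grey_panel> %d years (%d-%d), dependent '%s', %d factors\n",
    nrow(x), min(x$year), max(x$year), panel_dependent(x), length(panel_factors(x))
  ))
  NextMethod()
}

#' Accessors for panel components
#'
#' @param panel A [grey_panel()].
#' @return `panel_dependent()` and `panel_factors()` return column names;
#'   `panel_years()` the year vector; `panel_series()` a named list of the
#'   numeric series with the dependent first.
#' @export
panel_dependent <- function(panel) attr(panel, "dependent")

#' @rdname panel_dependent
#' @export
panel_factors <- function(panel) attr(panel, "factors")

#' @rdname panel_dependent
#' @export
panel_years <- function(panel) panel$year

#' @rdname panel_dependent
#' @export
panel_series <- function(panel) {
  ids <- c(panel_dependent(panel), panel_factors(panel))
  setNames(lapply(ids, function(cl) panel[[cl]]), ids)
}

#' Read / write a series panel as wide CSV
#'
#' The on-disk format is a plain wide CSV: a `year` column plus named numeric
#' count columns. `write_panel()` followed by `read_panel()` is lossless for
#' any valid panel.
#'
#' @param path CSV file path.
#' @param dependent Name of the dependent column.
#' @param labels Optional factor labels, as in [grey_panel()].
#' @return `read_panel()` returns a validated [grey_panel()];
#'   `write_panel()` returns `path` invisibly.
#' @export
read_panel <- function(path, dependent, labels = NULL) {
  check(file.exists(path), sprintf("file '%s' does not exist", path), "io")
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  grey_panel(data, dependent = dependent, labels = labels)
}

#' @rdname read_panel
#' @param panel A [grey_panel()] to serialize.
#' @export
write_panel <- function(panel, path) {
  check(is.character(path) && length(path) == 1 && nzchar(path),
        "`path` must be a non-empty file path", "io")
  check(dir.exists(dirname(path)),
        sprintf("directory '%s' does not exist", dirname(path)), "io")
  readr::write_csv(as_tibble(panel), path, progress = FALSE)
  invisible(path)
}

#' Michigan roundabout crash panel, 2016-2021
#'
#' Annual police-reported traffic crashes at Michigan roundabouts together
#' with eight explanatory count series: crashes on snow-covered roads (X1),
#' head-on crashes against a left-turning vehicle (X2), sideswipe crashes
#' (X3), crashes with distracted drivers (X4), injury crashes (X5), crashes
#' in the road median (X6), crashes involving buses or trucks (X7), and
#' crashes in rainy weather (X8). This short (n = 6), positive, strongly
#' fluctuating panel is the canonical worked example for the package and the
#' regression anchor for its tests. The same table ships as a CSV under
#' `inst/extdata/michigan_roundabouts.csv`.
#'
#' @return A [grey_panel()] with dependent `total` and factors `X1`..`X8`.
#' @examples
#' michigan_roundabouts()
#' @export
michigan_roundabouts <- function() {
  grey_panel(
    tibble(
      year  = 2016:2021,
      total = c(489, 1510, 1501, 1864, 1300, 1730),
      X1    = c(20, 73, 78, 85, 61, 79),
      X2    = c(1, 3, 3, 5, 2, 1),
      X3    = c(146, 535, 523, 642, 416, 618),
      X4    = c(23, 48, 41, 57, 49, 56),
      X5    = c(48, 125, 116, 146, 103, 132),
      X6    = c(5, 19, 16, 19, 19, 23),
      X7    = c(25, 97, 86, 162, 96, 131),
      X8    = c(52, 154, 112, 176, 77, 116)
    ),
    dependent = "total",
    labels = c(
      X1 = "snow-covered road", X2 = "head-on crash on left turn",
      X3 = "sideswipe", X4 = "distracted driver", X5 = "crash with injury",
      X6 = "crash on median", X7 = "buses/trucks crash", X8 = "rainy weather"
    )
  )
}
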