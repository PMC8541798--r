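#' Project a user total with the market-revenue index
#'
#' Projects the global number of users from the base year to a target year
#' in proportion to the market-revenue index. Two readings of the
#' market-to-users link are implemented:
#'
#' * `mode = "index"` (default): `total * ratio(target)`, where `ratio` is
#'   the index calibrated at `base_year`. This is direct proportionality —
#'   a 17% revenue rise implies 17% more users.
#' * `mode = "damped"`: `total * (1 + rho * (ratio(target) - 1))`, shrinking
#'   the index's relative change toward zero by the revenue-prevalence
#'   correlation `rho`. For `rho` in (0, 1) the damped projection always lies
#'   between the base total and the index-mode projection.
#'
#' Either mode returns the base total exactly when `target_year == base_year`.
#'
#' @param total User count at the base year.
#' @param index A market index tibble ([market_index()] /
#'   [read_market_index()]); calibration at `base_year` is applied here.
#' @param target_year Year to project to (must be in the series).
#' @param base_year Calibration year (default 2018; must be in the series).
#' @param mode `"index"` or `"damped"`.
#' @param rho Revenue-prevalence Pearson correlation used by `"damped"`
#'   mode, in `[-1, 1]` (default 0.933, estimated from a national series
#'   where both revenue and prevalence are observed; see
#'   [pearson_correlation()] to recompute it from your own data).
#' @return The projected user count (a single number).
#' @examples
#' idx <- market_index(c(2018, 2020), c(100, 117))
#' project_total(58107606, idx, target_year = 2020)
#' @export
project_total <- function(total, index, target_year, base_year = 2018,
                          mode = c("index", "damped"), rho = 0.933) {
  mode <- match.arg(mode)
  if (!is.numeric(total) || length(total) != 1 || is.na(total) || total < 0) {
    abort("`total` must be a single non-negative number.")
  }
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) || abs(rho) > 1) {
    abort("`rho` must be a single correlation coefficient in [-1, 1].")
  }
  calibrated <- calibrate_index(index, base_year = base_year)
  ratio <- calibrated$ratio[calibrated$year == target_year]
  if (length(ratio) != 1) {
    abort(sprintf("Target year %d is not in the index series.", target_year))
  }
  if (target_year == base_year) return(total)
  switch(mode,
    index = total * ratio,
    damped = total * (1 + rho * (ratio - 1))
  )
}

#' Project a user total to every year of an index series
#'
#' Runs [project_total()] for each year of the series and reports both modes
#' side by side, so the direct-proportionality and correlation-damped
#' readings can be compared.
#'
#' @inheritParams project_total
#' @return A `projection_series` tibble: `year`, `index_pct`, `ratio`,
#'   `projected_index`, `projected_damped`.
#' @examples
#' idx <- market_index(c(2018, 2019, 2020), c(100, 110, 117))
#' project_series(58107606, idx)
#' @export
project_series <- function(total, index, base_year = 2018, rho = 0.933) {
  calibrated <- calibrate_index(index, base_year = base_year)
  out <- calibrated |>
    dplyr::mutate(
      projected_index = purrr::map_dbl(
        .data$year, ~ project_total(total, index, .x, base_year, "index", rho)),
      projected_damped = purrr::map_dbl(
        .data$year, ~ project_total(total, index, .x, base_year, "damped", rho))
    )
  structure(out,
    class = c("projection_series", class(tibble::tibble())),
    base_year = base_year, base_total = total, rho = rho
  )
}

#' @describeIn project_series Line plot of both projection modes over time.
#' @param object A `projection_series` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.projection_series <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      c("projected_index", "projected_damped"),
      names_to = "mode", values_to = "projected",
      names_prefix = "projected_"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$projected / 1e6,
                                     colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "base_year"), linetype = 2,
                        colour = "grey60") +
    ggplot2::labs(
      x = "year", y = "projected users (millions)", colour = "mode",
      title = "Projected worldwide user total by market-revenue index"
    ) +
    ggplot2::theme_minimal()
}

#' Pearson correlation between two year-indexed series
#'
#' Product-moment correlation over the intersection of years, the diagnostic
#' used to justify projecting user totals from market revenue. Requires at
#' least three overlapping years and non-constant values on the overlap.
#'
#' @param series_a,series_b Data frames whose first two columns are year and
#'   value (e.g. per-capita revenue and prevalence).
#' @return The correlation coefficient, a single number in `[-1, 1]`.
#' @examples
#' a <- data.frame(year = 2015:2019, value = 1:5)
#' b <- data.frame(year = 2015:2019, value = 2 * (1:5) + 1)
#' pearson_correlation(a, b)
#' @export
pearson_correlation <- function(series_a, series_b) {
  as_series <- function(x, lab) {
    if (!is.data.frame(x) || ncol(x) < 2) {
      abort(sprintf("`%s` must be a data frame with year and value columns.", lab))
    }
    tibble::tibble(year = x[[1]], value = as.numeric(x[[2]]))
  }
  a <- as_series(series_a, "series_a")
  b <- as_series(series_b, "series_b")
  overlap <- dplyr::inner_join(a, b, by = "year", suffix = c("_a", "_b"))
  if (nrow(overlap) < 3) {
    abort("Fewer than 3 overlapping years between the two series.")
  }
  if (stats::sd(overlap$value_a) == 0 || stats::sd(overlap$value_b) == 0) {
    abort("A series is constant on the overlapping years; correlation is undefined.")
  }
  stats::cor(overlap$value_a, overlap$value_b)
}
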