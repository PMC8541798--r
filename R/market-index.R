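#' Build a market-revenue index series
#'
#' A market-revenue index expresses e-cigarette market revenue by year as a
#' percentage of a reference year's revenue. The series drives the forward
#' projection of the global user total (see [project_total()]).
#'
#' @param years Integer vector of calendar years (no duplicates).
#' @param index_pct Positive index values in percent.
#' @return A tibble with columns `year` and `index_pct`.
#' @export
market_index <- function(years, index_pct) {
  if (length(years) != length(index_pct)) {
    abort("`years` and `index_pct` must have the same length.")
  }
  tbl <- tibble::tibble(year = as.integer(years), index_pct = as.numeric(index_pct))
  dup <- unique(tbl$year[duplicated(tbl$year)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate year(s) in market index: %s.", paste(dup, collapse = ", ")))
  }
  if (any(is.na(tbl$index_pct)) || any(tbl$index_pct <= 0)) {
    abort("Every market index value must be a positive number.")
  }
  dplyr::arrange(tbl, .data$year)
}

#' Read a market-revenue index from CSV
#'
#' @param source Path to a CSV with columns `year` and `index_pct`
#'   (index in percent of a reference year).
#' @return A tibble with columns `year` and `index_pct`.
#' @examples
#' idx <- read_market_index(
#'   system.file("extdata", "market_index_2012_2023.csv", package = "prevcascade")
#' )
#' calibrate_index(idx, base_year = 2018)
#' @export
read_market_index <- function(source) {
  raw <- readr::read_csv(source, col_types = readr::cols(
    year = readr::col_integer(), index_pct = readr::col_double()
  ), progress = FALSE)
  if (!all(c("year", "index_pct") %in% names(raw))) {
    abort("Market index CSV needs columns \"year\" and \"index_pct\".")
  }
  market_index(raw$year, raw$index_pct)
}

#' Calibrate an index series to a base year
#'
#' Divides every index value by the base-year value so the base year maps to
#' a ratio of exactly 1. Calibration is idempotent: re-calibrating at the
#' same year changes nothing.
#'
#' @param index A market index tibble ([market_index()]).
#' @param base_year Calendar year present in the series (default 2018).
#' @return The index tibble with an added `ratio` column (base year = 1).
#' @export
calibrate_index <- function(index, base_year = 2018) {
  index <- market_index(index$year, index$index_pct)
  base <- index$index_pct[index$year == base_year]
  if (length(base) != 1) {
    abort(sprintf("Base year %d is not in the index series.", base_year))
  }
  dplyr::mutate(index, ratio = .data$index_pct / base)
}
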