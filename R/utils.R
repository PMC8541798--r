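#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used in the
#' package's printed percentage and user-count tables. Base [round()] uses
#' round-half-to-even, which would print 48.585 as 48.58.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(48.585, 2)
#' round_half_up(2.5)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a count with thousands separators
#'
#' @param x Numeric vector of counts.
#' @return Character vector like `"58,107,606"`; counts are rounded half-up
#'   to integers first.
#' @export
format_count <- function(x) {
  formatC(round_half_up(x), format = "f", digits = 0, big.mark = ",")
}

# internal: stop with a labelled stage prefix so pipeline errors name their origin
stage_abort <- function(stage, msg) {
  abort(paste0("[", stage, "] ", msg))
}
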