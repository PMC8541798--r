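#' Recognised factor levels
#'
#' The three similarity factors used throughout the package, with their
#' accepted labels. "unknown" is a first-class level of every factor: a
#' country whose region, income group or legal status is not known still
#' carries that information explicitly, is grouped into "Unknown" report rows,
#' and is skipped at cascade levels whose key would need the missing factor.
#'
#' @format A named list of character vectors with elements `who_region`
#'   (six WHO regions plus "unknown"), `income_group` (four World Bank income
#'   classes plus "unknown") and `legal_status` (e-cigarette sale allowed,
#'   banned, or no specific law, plus "unknown").
#' @export
factor_levels <- list(
  who_region = c(
    "African", "Eastern Mediterranean", "European", "Americas",
    "South-East Asia", "Western Pacific", "unknown"
  ),
  income_group = c("high", "upper middle", "lower middle", "low", "unknown"),
  legal_status = c("allowed", "banned", "no specific law", "unknown")
)

#' @rdname factor_levels
#' @export
similarity_factors <- names(factor_levels)

# internal: validate one factor column, hard error listing accepted labels
check_factor_column <- function(x, factor_name) {
  accepted <- factor_levels[[factor_name]]
  bad <- setdiff(unique(x), accepted)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unrecognized %s label(s): %s. Accepted labels: %s.",
      factor_name,
      paste0("\"", bad, "\"", collapse = ", "),
      paste0("\"", accepted, "\"", collapse = ", ")
    ))
  }
  invisible(x)
}

# internal: report label for a factor level ("unknown" -> "Unknown")
report_label <- function(x) ifelse(x == "unknown", "Unknown", x)
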