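#' Convert prevalence to a user count
#'
#' The number of current users in a country is its prevalence times its
#' adult (15+) population. Kept as a real number internally; rounding to
#' whole persons happens only in printed reports.
#'
#' @param prevalence Fraction(s) in `[0, 1]`.
#' @param adult_population Non-negative population count(s).
#' @return Numeric vector of user counts.
#' @examples
#' vapers_count(0.02, 1e6)
#' @export
vapers_count <- function(prevalence, adult_population) {
  if (any(is.na(prevalence)) || any(prevalence < 0 | prevalence > 1)) {
    abort("`prevalence` must be fractions in [0, 1].")
  }
  if (any(is.na(adult_population)) || any(adult_population < 0)) {
    abort("`adult_population` must be non-negative.")
  }
  prevalence * adult_population
}

#' Aggregate user counts into report rows
#'
#' Scales every country's (observed or imputed) prevalence by its adult
#' population and sums the resulting user counts over a partition of the
#' world: one similarity factor (countries with an "unknown" level form an
#' "Unknown" row), the surveyed/estimated split, or the world as a single
#' row. Un-rounded sums are conserved: every partition totals exactly the
#' world figure.
#'
#' @param fit A [cascade_impute()] result covering every country in `world`.
#' @param world The validated world table the fit was computed from.
#' @param by `"world"`, one of `"who_region"`, `"income_group"`,
#'   `"legal_status"`, or `"survey_status"` (countries with data from surveys
#'   vs countries with estimated data).
#' @return A tibble with columns `group`, `n_countries`, `n_vapers`
#'   (un-rounded real counts).
#' @examples
#' sim <- generate_world(synthetic_config(n_countries = 50), seed = 1)
#' fit <- cascade_impute(sim$observed)
#' aggregate_estimates(fit, sim$observed, by = "income_group")
#' @export
aggregate_estimates <- function(fit, world, by = "world") {
  world <- validate_world_table(world)
  choices <- c("world", similarity_factors, "survey_status")
  if (!is.character(by) || length(by) != 1 || !by %in% choices) {
    abort(sprintf("`by` must be one of: %s.", paste0("\"", choices, "\"", collapse = ", ")))
  }
  fit_tbl <- tibble::as_tibble(fit)[c("iso3", "prevalence", "level")]
  missing <- setdiff(world$iso3, fit_tbl$iso3)
  if (length(missing) > 0) {
    stage_abort("aggregate", sprintf(
      "No imputed/observed value for: %s.", paste(missing, collapse = ", ")))
  }
  joined <- world |>
    dplyr::select(-"prevalence") |>
    dplyr::inner_join(fit_tbl, by = "iso3") |>
    dplyr::mutate(n_vapers = vapers_count(.data$prevalence, .data$adult_population))

  grouped <- switch(by,
    world = dplyr::mutate(joined, group = "World"),
    survey_status = dplyr::mutate(joined, group = ifelse(
      .data$level == 0L,
      "Countries with data from surveys",
      "Countries with estimated data"
    )),
    dplyr::mutate(joined, group = report_label(.data[[by]]))
  )
  out <- grouped |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_countries = dplyr::n(),
      n_vapers = sum(.data$n_vapers),
      .groups = "drop"
    )
  order_levels <- switch(by,
    world = "World",
    survey_status = c("Countries with data from surveys", "Countries with estimated data"),
    report_label(factor_levels[[by]])
  )
  dplyr::arrange(out, match(.data$group, order_levels))
}
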