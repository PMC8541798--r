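#' Column mapping for country tables
#'
#' Maps the canonical column names used internally to the column names found
#' in a particular CSV file, so tables from different providers can be read
#' without editing the file.
#'
#' @param iso3,name,who_region,income_group,legal_status,adult_population
#'   Names of the corresponding columns in the file.
#' @param prevalence_pct Name of the optional prevalence column, in percent.
#' @param survey_year Name of the optional survey-year column.
#' @return A named character vector (canonical name -> file column name).
#' @export
country_schema <- function(iso3 = "iso3",
                           name = "name",
                           who_region = "who_region",
                           income_group = "income_group",
                           legal_status = "legal_status",
                           adult_population = "adult_population",
                           prevalence_pct = "prevalence_pct",
                           survey_year = "survey_year") {
  c(
    iso3 = iso3, name = name, who_region = who_region,
    income_group = income_group, legal_status = legal_status,
    adult_population = adult_population, prevalence_pct = prevalence_pct,
    survey_year = survey_year
  )
}

#' Read a country table from CSV
#'
#' Reads one row per country/territory: ISO code, the three similarity
#' factors (WHO region, World Bank income group, legal status of e-cigarette
#' sale), adult (15+) population, and, where a qualifying survey exists, the
#' current-use vaping prevalence and survey year. Prevalence is given in
#' percent in the file and stored as a fraction in `[0, 1]`; a missing
#' prevalence cell marks the country as unsurveyed.
#'
#' @param source Path to a CSV file (UTF-8, header row), or a connection.
#' @param schema Column mapping from [country_schema()].
#' @param survey_year_window Two integers: the inclusive window of acceptable
#'   survey years (inclusion criterion; default 2012-2020).
#' @return A validated world table: a tibble with columns `iso3`, `name`,
#'   `who_region`, `income_group`, `legal_status`, `adult_population`,
#'   `prevalence` (fraction, `NA` where unsurveyed) and `survey_year`.
#' @seealso [validate_world_table()], [coverage_summary()], [cascade_impute()]
#' @export
read_country_table <- function(source,
                               schema = country_schema(),
                               survey_year_window = c(2012, 2020)) {
  raw <- readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("iso3", "name", "who_region", "income_group",
                "legal_status", "adult_population")
  missing_cols <- schema[required][!schema[required] %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(sprintf("Country table is missing required column(s): %s.",
                  paste0("\"", missing_cols, "\"", collapse = ", ")))
  }

  get_col <- function(canonical) {
    file_col <- schema[[canonical]]
    if (!is.null(file_col) && file_col %in% names(raw)) raw[[file_col]] else NA_character_
  }

  prevalence_pct <- suppressWarnings(as.numeric(get_col("prevalence_pct")))
  tbl <- tibble::tibble(
    iso3 = get_col("iso3"),
    name = get_col("name"),
    who_region = tidyr::replace_na(get_col("who_region"), "unknown"),
    income_group = tidyr::replace_na(get_col("income_group"), "unknown"),
    legal_status = tidyr::replace_na(get_col("legal_status"), "unknown"),
    adult_population = suppressWarnings(as.numeric(get_col("adult_population"))),
    prevalence = prevalence_pct / 100,
    survey_year = suppressWarnings(as.integer(get_col("survey_year")))
  )
  if (any(!is.na(prevalence_pct) & (prevalence_pct < 0 | prevalence_pct > 100))) {
    bad <- tbl$iso3[!is.na(prevalence_pct) & (prevalence_pct < 0 | prevalence_pct > 100)]
    abort(sprintf("Prevalence outside [0, 100]%% for: %s.", paste(bad, collapse = ", ")))
  }
  validate_world_table(tbl, survey_year_window = survey_year_window)
}

#' Validate a world table
#'
#' Checks the invariants every downstream operation relies on: unique ISO
#' codes, recognised factor labels, non-negative adult populations,
#' prevalences (where present) in `[0, 1]`, and survey years (where present)
#' inside the inclusion window.
#'
#' @param world A data frame with the columns described in
#'   [read_country_table()].
#' @inheritParams read_country_table
#' @return The validated table as a tibble, invisibly usable in a pipe.
#' @export
validate_world_table <- function(world, survey_year_window = c(2012, 2020)) {
  world <- tibble::as_tibble(world)
  required <- c("iso3", "who_region", "income_group", "legal_status",
                "adult_population", "prevalence")
  missing_cols <- setdiff(required, names(world))
  if (length(missing_cols) > 0) {
    abort(sprintf("World table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"name" %in% names(world)) world$name <- world$iso3
  if (!"survey_year" %in% names(world)) world$survey_year <- NA_integer_

  dup <- unique(world$iso3[duplicated(world$iso3)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate iso3 code(s): %s.", paste(dup, collapse = ", ")))
  }
  if (any(is.na(world$iso3)) || any(nchar(world$iso3) != 3)) {
    abort("Every record needs a 3-letter iso3 code.")
  }
  for (f in similarity_factors) check_factor_column(world[[f]], f)
  if (any(is.na(world$adult_population)) || any(world$adult_population < 0)) {
    abort("adult_population must be a non-negative number for every record.")
  }
  p <- world$prevalence
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("Stored prevalence must be a fraction in [0, 1].")
  }
  yr <- world$survey_year
  bad_yr <- !is.na(p) & !is.na(yr) &
    (yr < survey_year_window[1] | yr > survey_year_window[2])
  if (any(bad_yr)) {
    abort(sprintf(
      "Survey year outside the %d-%d inclusion window for: %s.",
      survey_year_window[1], survey_year_window[2],
      paste(world$iso3[bad_yr], collapse = ", ")
    ))
  }
  world[c("iso3", "name", similarity_factors, "adult_population",
          "prevalence", "survey_year")]
}

#' Write a world table to CSV
#'
#' Inverse of [read_country_table()]: prevalence is written back in percent
#' under `prevalence_pct`, empty where the country is unsurveyed.
#'
#' @param world A validated world table.
#' @param path Output CSV path.
#' @return `world`, invisibly.
#' @export
write_country_table <- function(world, path) {
  world <- validate_world_table(world)
  out <- dplyr::mutate(world,
    prevalence_pct = .data$prevalence * 100,
    prevalence = NULL
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(world)
}

#' Survey population coverage summary
#'
#' How much of the adult population lives in surveyed vs unsurveyed
#' countries, worldwide or split by one similarity factor. Percentages are
#' of the row's total population and are rounded half-up to 2 decimal
#' places.
#'
#' @param world A validated world table.
#' @param by `"world"` for a single row, or one of `"who_region"`,
#'   `"income_group"`, `"legal_status"`.
#' @return A tibble with columns `group`, `surveyed_population`,
#'   `surveyed_pct`, `unsurveyed_population`, `unsurveyed_pct`.
#' @examples
#' world <- generate_world(synthetic_config(n_countries = 40), seed = 1)$observed
#' coverage_summary(world, by = "income_group")
#' @export
coverage_summary <- function(world, by = "world") {
  world <- validate_world_table(world)
  choices <- c("world", similarity_factors)
  if (!is.character(by) || length(by) != 1 || !by %in% choices) {
    abort(sprintf("`by` must be one of: %s.", paste0("\"", choices, "\"", collapse = ", ")))
  }
  grouped <- if (by == "world") {
    dplyr::mutate(world, group = "World")
  } else {
    dplyr::mutate(world, group = report_label(.data[[by]]))
  }
  out <- grouped |>
    dplyr::mutate(surveyed = !is.na(.data$prevalence)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      surveyed_population = sum(.data$adult_population[.data$surveyed]),
      unsurveyed_population = sum(.data$adult_population[!.data$surveyed]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      total = .data$surveyed_population + .data$unsurveyed_population,
      surveyed_pct = ifelse(.data$total > 0,
                            round_half_up(100 * .data$surveyed_population / .data$total, 2), 0),
      unsurveyed_pct = ifelse(.data$total > 0,
                              round_half_up(100 * .data$unsurveyed_population / .data$total, 2), 0),
      total = NULL
    )
  if (by != "world") {
    order_levels <- report_label(factor_levels[[by]])
    out <- dplyr::arrange(out, match(.data$group, order_levels))
  }
  out[c("group", "surveyed_population", "surveyed_pct",
        "unsurveyed_population", "unsurveyed_pct")]
}
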