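#' Run the full estimation pipeline
#'
#' Ties the stages together for one country table: validates it, summarises
#' survey coverage by every factor, computes the per-signature subgroup
#' statistics, runs the imputation cascade, and aggregates user counts over
#' the world, the three similarity factors and the surveyed/estimated split.
#' Deterministic for fixed inputs.
#'
#' @param countries A validated world table (data frame), or a path to a
#'   country CSV readable by [read_country_table()].
#' @param spec A [cascade_spec()].
#' @param z Normal quantile for goodness-of-fit intervals.
#' @param min_group_n,weight_by_population Passed to [cascade_impute()].
#' @param schema,survey_year_window Passed to [read_country_table()] when
#'   `countries` is a path.
#' @param verbose If `TRUE`, logs the cascade's cumulative coverage sequence.
#' @return A `vaping_report` list: `world` (the input table), `fit` (the
#'   cascade result), `coverage` (list of coverage tibbles: world and per
#'   factor), `group_stats` (list of subgroup-statistics tibbles, one per
#'   cascade signature), `estimates` (list of estimate tibbles: world, per
#'   factor, survey status), `cascade_coverage`, and `world_total`.
#' @examples
#' sim <- generate_world(synthetic_config(n_countries = 60), seed = 1)
#' report <- run_estimate(sim$observed)
#' report$world_total
#' glance(report)
#' @export
run_estimate <- function(countries, spec = cascade_spec(), z = 1.96,
                         min_group_n = 1, weight_by_population = FALSE,
                         schema = country_schema(),
                         survey_year_window = c(2012, 2020),
                         verbose = FALSE) {
  world <- if (is.character(countries)) {
    if (!file.exists(countries)) {
      stage_abort("input", sprintf("Country table not found: %s", countries))
    }
    read_country_table(countries, schema = schema,
                       survey_year_window = survey_year_window)
  } else {
    validate_world_table(countries, survey_year_window = survey_year_window)
  }

  coverage <- c(
    list(world = coverage_summary(world, "world")),
    setNames(
      lapply(similarity_factors, function(f) coverage_summary(world, f)),
      similarity_factors
    )
  )
  fit <- cascade_impute(world, spec = spec, z = z, min_group_n = min_group_n,
                        weight_by_population = weight_by_population)
  signature_label <- function(sig) {
    if (length(sig) == 0) "global" else paste(sig, collapse = " x ")
  }
  group_stats <- setNames(
    lapply(spec, function(sig) {
      compute_group_stats(world, sig, weight_by_population = weight_by_population)
    }),
    vapply(spec, signature_label, character(1))
  )
  estimates <- c(
    list(world = aggregate_estimates(fit, world, "world")),
    setNames(
      lapply(similarity_factors, function(f) aggregate_estimates(fit, world, f)),
      similarity_factors
    ),
    list(survey_status = aggregate_estimates(fit, world, "survey_status"))
  )
  cov_seq <- cascade_coverage(fit)
  if (isTRUE(verbose)) {
    message("cascade cumulative coverage: ",
            paste(cov_seq$cumulative, collapse = ", "))
  }
  structure(list(
    world = world,
    fit = fit,
    coverage = coverage,
    group_stats = group_stats,
    estimates = estimates,
    cascade_coverage = cov_seq,
    world_total = estimates$world$n_vapers
  ), class = "vaping_report")
}

#' @describeIn run_estimate All estimate rows as one long tibble with a
#'   `partition` column.
#' @param x A `vaping_report` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vaping_report <- function(x, ...) {
  dplyr::bind_rows(x$estimates, .id = "partition")
}

#' @describeIn run_estimate One-row summary: country counts, surveyed
#'   share of the adult population, and the world user total.
#' @exportS3Method generics::glance
glance.vaping_report <- function(x, ...) {
  cov <- x$coverage$world
  tibble::tibble(
    n_countries = nrow(x$world),
    n_surveyed = sum(!is.na(x$world$prevalence)),
    surveyed_population_pct = cov$surveyed_pct,
    world_total = x$world_total
  )
}

#' @export
print.vaping_report <- function(x, ...) {
  cov <- x$coverage$world
  cat("Global vaping estimate\n")
  cat("  countries:", nrow(x$world),
      sprintf("(%d surveyed, %d estimated)\n",
              sum(x$fit$level == 0), sum(x$fit$level > 0)))
  cat(sprintf("  surveyed share of adult population: %.2f%%\n", cov$surveyed_pct))
  cat("  world total:", format_count(x$world_total), "users\n")
  cat("  cascade cumulative coverage:",
      paste(x$cascade_coverage$cumulative, collapse = ", "), "\n\n")
  est <- x$estimates$income_group
  cat("  users by income group:\n")
  for (i in seq_len(nrow(est))) {
    cat(sprintf("    %-14s %4d countries  %15s\n", est$group[i],
                est$n_countries[i], format_count(est$n_vapers[i])))
  }
  invisible(x)
}

#' @describeIn run_estimate Survey population coverage by income group
#'   (surveyed vs unsurveyed shares).
#' @param object A `vaping_report` object.
#' @exportS3Method ggplot2::autoplot
autoplot.vaping_report <- function(object, ...) {
  long <- object$coverage$income_group |>
    tidyr::pivot_longer(c("surveyed_pct", "unsurveyed_pct"),
                        names_to = "status", values_to = "pct") |>
    dplyr::mutate(status = ifelse(.data$status == "surveyed_pct",
                                  "surveyed", "not surveyed"))
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$pct, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "income group", y = "share of adult population (%)",
      title = "Survey coverage of the adult population by income group"
    ) +
    ggplot2::theme_minimal()
}

#' Write a report bundle to CSV files
#'
#' Writes the coverage tables, subgroup statistics, imputation provenance
#' and estimate tables of a [run_estimate()] bundle into a directory, one
#' CSV per table, with user counts rounded half-up to whole persons.
#' Outputs are byte-identical across runs for identical inputs.
#'
#' @param report A `vaping_report` from [run_estimate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "vaping_report")) {
    abort("`report` must come from run_estimate().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(tbl, file) {
    path <- file.path(dir, file)
    readr::write_csv(tbl, path, na = "", progress = FALSE)
    paths <<- c(paths, path)
  }
  for (nm in names(report$coverage)) {
    emit(report$coverage[[nm]], paste0("coverage_", gsub(" ", "_", nm), ".csv"))
  }
  for (nm in names(report$group_stats)) {
    stats <- dplyr::mutate(report$group_stats[[nm]],
                           mean_prevalence_pct = .data$mean_prevalence * 100)
    emit(stats, paste0("group_stats_", gsub("[ x]+", "_", nm), ".csv"))
  }
  write_provenance(report$fit, file.path(dir, "provenance.csv"))
  paths <- c(paths, file.path(dir, "provenance.csv"))
  for (nm in names(report$estimates)) {
    est <- dplyr::mutate(report$estimates[[nm]],
                         n_vapers = round_half_up(.data$n_vapers))
    emit(est, paste0("estimates_", nm, ".csv"))
  }
  emit(report$cascade_coverage, "cascade_coverage.csv")
  invisible(paths)
}

#' Project a report's world total across an index series
#'
#' Convenience wrapper: takes the world total of a [run_estimate()] bundle
#' (or a bare number) and an index series and reports both projection modes
#' for every year.
#'
#' @param base_total A `vaping_report` or a single base-year user count.
#' @param index A market index tibble or a path to an index CSV.
#' @inheritParams project_series
#' @return A `projection_series` tibble (see [project_series()]).
#' @examples
#' idx <- market_index(2018:2020, c(100, 110, 117))
#' run_project(58107606, idx)
#' @export
run_project <- function(base_total, index, base_year = 2018, rho = 0.933) {
  total <- if (inherits(base_total, "vaping_report")) {
    base_total$world_total
  } else {
    base_total
  }
  if (is.character(index)) {
    if (!file.exists(index)) {
      stage_abort("input", sprintf("Market index not found: %s", index))
    }
    index <- read_market_index(index)
  }
  project_series(total, index, base_year = base_year, rho = rho)
}

#' Read a pipeline run configuration from YAML
#'
#' A run configuration names the input files and the tunables: country and
#' index CSV paths, a column mapping, the survey-year window, the base year,
#' `z`, and `rho`. Referenced inputs must exist before any computation runs.
#'
#' @param path Path to a YAML file. Recognised keys: `countries`, `index`,
#'   `columns` (mapping for [country_schema()]), `survey_year_window`,
#'   `base_year`, `z`, `rho`, `min_group_n`.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stage_abort("config", sprintf("Config not found: %s", path))
  raw <- yaml::read_yaml(path)
  schema <- do.call(country_schema, as.list(raw$columns %||% list()))
  cfg <- list(
    countries = raw$countries %||% NULL,
    index = raw$index %||% NULL,
    schema = schema,
    survey_year_window = unlist(raw$survey_year_window %||% c(2012, 2020)),
    base_year = raw$base_year %||% 2018,
    z = raw$z %||% 1.96,
    rho = raw$rho %||% 0.933,
    min_group_n = raw$min_group_n %||% 1
  )
  for (key in c("countries", "index")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stage_abort("config", sprintf("Configured %s file not found: %s",
                                    key, cfg[[key]]))
    }
  }
  cfg
}
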