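#' Define an imputation cascade
#'
#' An ordered list of factor signatures tried in turn when filling an
#' unsurveyed country: earlier signatures are more specific. The default is
#' the narrative order of the average-similarity method — the full
#' three-factor breakdown, then income x legal status, income x region,
#' region x legal status, income alone, and finally the global mean over all
#' surveyed countries (the empty signature), which guarantees the cascade
#' always terminates with full coverage.
#'
#' @param signatures A list of character vectors, each a subset of
#'   `c("who_region", "income_group", "legal_status")`. The last entry must
#'   be the empty signature `character(0)` (the global mean).
#' @return An object of class `cascade_spec`.
#' @examples
#' cascade_spec()
#' # region-first variant
#' cascade_spec(list(
#'   c("who_region", "income_group"), "who_region", character(0)
#' ))
#' @export
cascade_spec <- function(signatures = list(
                           c("who_region", "income_group", "legal_status"),
                           c("income_group", "legal_status"),
                           c("income_group", "who_region"),
                           c("who_region", "legal_status"),
                           "income_group",
                           character(0)
                         )) {
  if (!is.list(signatures) || length(signatures) == 0) {
    abort("`signatures` must be a non-empty list of character vectors.")
  }
  signatures <- lapply(signatures, as.character)
  for (sig in signatures) {
    bad <- setdiff(sig, similarity_factors)
    if (length(bad) > 0) {
      abort(sprintf("Unknown factor(s) in cascade signature: %s.",
                    paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(sig)) abort("A cascade signature may not repeat a factor.")
  }
  if (length(signatures[[length(signatures)]]) != 0) {
    abort("The last cascade signature must be the empty (global) signature.")
  }
  structure(signatures, class = "cascade_spec")
}

#' @export
print.cascade_spec <- function(x, ...) {
  cat("Imputation cascade (", length(x), " levels):\n", sep = "")
  for (i in seq_along(x)) {
    lab <- if (length(x[[i]]) == 0) "<global mean>" else paste(x[[i]], collapse = " x ")
    cat(sprintf("  level %d: %s\n", i, lab))
  }
  invisible(x)
}

#' Subgroup prevalence statistics
#'
#' For one factor signature, the unweighted mean, count and sample standard
#' deviation of observed prevalences across the surveyed countries in each
#' subgroup. Countries with an "unknown" level on any signature factor cannot
#' form a valid key and do not contribute. The empty signature yields the
#' single global row over all surveyed countries.
#'
#' @param world A validated world table.
#' @param signature Character vector of factor names (possibly empty).
#' @param weight_by_population If `TRUE`, means are weighted by adult
#'   population instead of one-country-one-value (default `FALSE`).
#' @return A tibble with the signature columns plus `mean_prevalence`
#'   (fraction), `n` (contributing surveyed countries) and `sd` (sample
#'   standard deviation of contributions, `NA` when `n < 2`). Empty when no
#'   subgroup has a surveyed country.
#' @examples
#' world <- generate_world(synthetic_config(n_countries = 60), seed = 1)$observed
#' compute_group_stats(world, "income_group")
#' @export
compute_group_stats <- function(world, signature, weight_by_population = FALSE) {
  world <- validate_world_table(world)
  signature <- as.character(signature)
  bad <- setdiff(signature, similarity_factors)
  if (length(bad) > 0) {
    abort(sprintf("Unknown factor(s) in signature: %s.", paste(bad, collapse = ", ")))
  }
  surveyed <- dplyr::filter(world, !is.na(.data$prevalence))
  for (f in signature) surveyed <- dplyr::filter(surveyed, .data[[f]] != "unknown")
  surveyed |>
    dplyr::group_by(dplyr::across(dplyr::all_of(signature))) |>
    dplyr::summarise(
      mean_prevalence = if (weight_by_population) {
        sum(.data$prevalence * .data$adult_population) / sum(.data$adult_population)
      } else {
        mean(.data$prevalence)
      },
      n = dplyr::n(),
      sd = if (dplyr::n() >= 2) stats::sd(.data$prevalence) else NA_real_,
      .groups = "drop"
    )
}

#' Goodness-of-fit interval for a group mean
#'
#' A simplified confidence interval for a subgroup mean prevalence, built
#' from the group's standard deviation and size:
#' `mean +/- z * sd / sqrt(n)`, truncated below at 0. With fewer than two
#' contributing countries the standard deviation — and hence the interval —
#' is unavailable and `NA` is returned, flagging a mean whose reliability
#' cannot be characterised (several strata rest on a single survey).
#'
#' @param mean_prevalence Group mean prevalence(s), as fractions.
#' @param sd Sample standard deviation(s) of the contributions.
#' @param n Number(s) of contributing surveyed countries.
#' @param z Positive normal quantile (default 1.96, a nominal 95% band).
#' @return A tibble with columns `lower` and `upper` (fractions; `NA` rows
#'   where `n < 2`).
#' @examples
#' fit_interval(0.02, 0.01, 4)
#' @export
fit_interval <- function(mean_prevalence, sd, n, z = 1.96) {
  if (!is.numeric(z) || length(z) != 1 || is.na(z) || z <= 0) {
    abort("`z` must be a single positive number.")
  }
  half <- z * sd / sqrt(n)
  lower <- pmax(mean_prevalence - half, 0)
  upper <- mean_prevalence + half
  usable <- !is.na(n) & n >= 2 & !is.na(sd)
  tibble::tibble(
    lower = ifelse(usable, lower, NA_real_),
    upper = ifelse(usable, upper, NA_real_)
  )
}

#' Impute prevalence through the fallback cascade
#'
#' Fills every unsurveyed country with the mean prevalence of the first
#' cascade level whose subgroup (built from the country's non-"unknown"
#' factors) contains at least `min_group_n` surveyed countries. Surveyed
#' countries pass through untouched at level 0. Each filled value carries its
#' provenance — the level and subgroup key that produced it — and, where the
#' subgroup has two or more contributors, a goodness-of-fit interval.
#'
#' @param world A validated world table with at least one surveyed country.
#' @param spec A [cascade_spec()]; the default reproduces the standard
#'   narrative order.
#' @param z Normal quantile for the goodness-of-fit interval (default 1.96).
#' @param min_group_n Minimum surveyed countries a subgroup needs before its
#'   mean is used (default 1: even a single-survey stratum wins over later,
#'   coarser levels). The terminal global mean ignores this threshold so the
#'   cascade always completes.
#' @param weight_by_population Passed to [compute_group_stats()].
#' @return A `cascade_imputation` tibble, one row per country, sorted by
#'   `iso3`: `iso3`, `prevalence` (fraction), `level` (0 = observed,
#'   1..k = cascade level), `group_key` (e.g. `"income_group=high"`, `NA`
#'   at level 0, `"global"` at the terminal level), `n_group`, `sd_group`,
#'   `interval_lower`, `interval_upper`, `observed`. The cascade spec and
#'   `z` are attached as attributes.
#' @examples
#' sim <- generate_world(synthetic_config(n_countries = 50), seed = 1)
#' fit <- cascade_impute(sim$observed)
#' cascade_coverage(fit)
#' @export
cascade_impute <- function(world, spec = cascade_spec(), z = 1.96,
                           min_group_n = 1, weight_by_population = FALSE) {
  world <- validate_world_table(world)
  if (!inherits(spec, "cascade_spec")) spec <- cascade_spec(spec)
  if (!is.numeric(min_group_n) || min_group_n < 1) {
    abort("`min_group_n` must be at least 1.")
  }
  if (sum(!is.na(world$prevalence)) == 0) {
    stage_abort("cascade", "No surveyed country: there is no basis for any group mean.")
  }

  result <- world |>
    dplyr::transmute(
      iso3 = .data$iso3,
      prevalence = .data$prevalence,
      level = ifelse(is.na(.data$prevalence), NA_integer_, 0L),
      group_key = NA_character_,
      n_group = NA_integer_,
      sd_group = NA_real_,
      interval_lower = NA_real_,
      interval_upper = NA_real_,
      observed = !is.na(.data$prevalence)
    )

  for (i in seq_along(spec)) {
    sig <- spec[[i]]
    is_global <- length(sig) == 0
    stats <- compute_group_stats(world, sig, weight_by_population = weight_by_population)
    if (!is_global) stats <- dplyr::filter(stats, .data$n >= min_group_n)
    if (nrow(stats) == 0) next

    pending <- is.na(result$level)
    if (!any(pending)) break
    candidates <- world[pending, c("iso3", sig), drop = FALSE]
    if (!is_global) {
      keep <- rep(TRUE, nrow(candidates))
      for (f in sig) keep <- keep & candidates[[f]] != "unknown"
      candidates <- candidates[keep, , drop = FALSE]
      matched <- dplyr::inner_join(candidates, stats, by = sig)
      if (nrow(matched) == 0) next
      matched$group_key <- apply(
        matched[sig], 1L,
        function(vals) paste(paste0(sig, "=", vals), collapse = "|")
      )
    } else {
      matched <- dplyr::cross_join(candidates, stats)
      matched$group_key <- "global"
    }
    ci <- fit_interval(matched$mean_prevalence, matched$sd, matched$n, z = z)
    idx <- match(matched$iso3, result$iso3)
    result$prevalence[idx] <- matched$mean_prevalence
    result$level[idx] <- i
    result$group_key[idx] <- matched$group_key
    result$n_group[idx] <- matched$n
    result$sd_group[idx] <- matched$sd
    result$interval_lower[idx] <- ci$lower
    result$interval_upper[idx] <- ci$upper
  }

  result <- dplyr::arrange(result, .data$iso3)
  structure(result,
    class = c("cascade_imputation", class(tibble::tibble())),
    cascade_spec = spec, z = z
  )
}

#' Per-level coverage of a cascade result
#'
#' How many countries received their value at each cascade level, and the
#' cumulative number of countries covered once each level has run — the
#' "information growth" profile of the estimation (level 0 is the surveyed
#' baseline).
#'
#' @param fit A [cascade_impute()] result.
#' @return A tibble with `level`, `n_countries`, and `cumulative`; every
#'   level of the spec appears (zero rows included), the cumulative column is
#'   non-decreasing and ends at the total number of countries.
#' @export
cascade_coverage <- function(fit) {
  if (!inherits(fit, "cascade_imputation")) {
    abort("`fit` must be the result of cascade_impute().")
  }
  spec <- attr(fit, "cascade_spec")
  all_levels <- tibble::tibble(level = 0:length(spec))
  fit |>
    tibble::as_tibble() |>
    dplyr::count(.data$level, name = "n_countries") |>
    dplyr::right_join(all_levels, by = "level") |>
    dplyr::mutate(n_countries = tidyr::replace_na(.data$n_countries, 0L)) |>
    dplyr::arrange(.data$level) |>
    dplyr::mutate(cumulative = cumsum(.data$n_countries))
}

#' @describeIn cascade_impute Provenance table as a plain tibble, with
#'   prevalence and interval bounds also expressed in percent for reporting.
#' @param x A `cascade_imputation` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cascade_imputation <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(
      value_pct = .data$prevalence * 100,
      interval_lower_pct = .data$interval_lower * 100,
      interval_upper_pct = .data$interval_upper * 100
    )
}

#' @describeIn cascade_impute One-row summary: country counts, how many were
#'   observed vs imputed, and the deepest cascade level used.
#' @exportS3Method generics::glance
glance.cascade_imputation <- function(x, ...) {
  tibble::tibble(
    n_countries = nrow(x),
    n_observed = sum(x$observed),
    n_imputed = sum(!x$observed),
    max_level = max(x$level),
    mean_prevalence_pct = mean(x$prevalence) * 100
  )
}

#' @describeIn cascade_impute Bar chart of countries filled per cascade
#'   level with the cumulative coverage overlaid.
#' @param object A `cascade_imputation` object.
#' @exportS3Method ggplot2::autoplot
autoplot.cascade_imputation <- function(object, ...) {
  cov <- cascade_coverage(object)
  ggplot2::ggplot(cov, ggplot2::aes(x = factor(.data$level))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_countries), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative, group = 1), colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::labs(
      x = "cascade level (0 = observed)",
      y = "countries",
      title = "Information growth across cascade levels",
      subtitle = "bars: countries filled at each level; line: cumulative coverage"
    ) +
    ggplot2::theme_minimal()
}

#' Export imputation provenance to CSV
#'
#' Writes the per-country provenance table (values and interval bounds in
#' percent) for downstream inspection.
#'
#' @param fit A [cascade_impute()] result.
#' @param path Output CSV path.
#' @return `fit`, invisibly.
#' @export
write_provenance <- function(fit, path) {
  out <- tidy(fit)[c("iso3", "value_pct", "level", "group_key",
                     "n_group", "interval_lower_pct", "interval_upper_pct")]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(fit)
}
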