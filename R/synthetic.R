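#' Configuration for the synthetic world generator
#'
#' Defines the statistical structure of a generated country table. True
#' prevalences follow a logit-additive model — baseline log-odds plus
#' region, income and legal-status effects plus country-level Gaussian noise
#' on the log-odds scale — the simplest structure under which "similar
#' countries have similar prevalence" holds exactly, with `noise_sd`
#' controlling how badly the similarity assumption fails. Adult populations
#' are log-normal with income-group-specific locations; survey availability
#' depends on income group, echoing the real pattern where high-income
#' populations are almost fully surveyed and low-income populations barely
#' at all.
#'
#' @param n_countries Number of countries/territories (default 201).
#' @param region_probs,income_probs,legal_probs Named marginal probabilities
#'   over each factor's levels (including `"unknown"`); each must sum to 1.
#'   Defaults approximate the real distribution of countries over WHO
#'   regions, World Bank income classes, and e-cigarette legal status, with
#'   a small unknown mass.
#' @param baseline_prevalence Prevalence implied by the baseline log-odds
#'   when all effects and noise are zero (default 0.015, i.e. 1.5%).
#' @param region_effects,income_effects,legal_effects Named additive effects
#'   on the log-odds scale; defaults reproduce the observed ordering (higher
#'   income and permissive regulation -> higher vaping prevalence).
#' @param noise_sd Country-level log-odds noise standard deviation
#'   (default 0.5).
#' @param pop_meanlog,pop_sdlog Log-normal location (per income group,
#'   named) and scale of adult populations; defaults span roughly 1e5-1e9
#'   persons.
#' @param survey_probs Named probability that a country of each income group
#'   has a qualifying survey (defaults ~0.87 / 0.77 / 0.09 / 0.055 for
#'   high / upper middle / lower middle / low).
#' @param survey_prob_pop_exponent Optional population-size dependence of
#'   survey availability: each country's probability is multiplied by
#'   `(population / median population)^exponent` and clipped to `[0, 1]`
#'   (default 0, no dependence).
#' @param survey_noise_sd Optional measurement noise (log-odds scale) added
#'   to observed prevalences; 0 (default) makes surveys report truth
#'   exactly.
#' @param survey_year_range Inclusive range survey years are drawn from.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_countries = 201,
                             region_probs = c(
                               "African" = 0.24, "Eastern Mediterranean" = 0.10,
                               "European" = 0.265, "Americas" = 0.175,
                               "South-East Asia" = 0.055, "Western Pacific" = 0.155,
                               "unknown" = 0.01
                             ),
                             income_probs = c(
                               "high" = 0.28, "upper middle" = 0.27,
                               "lower middle" = 0.24, "low" = 0.20,
                               "unknown" = 0.01
                             ),
                             legal_probs = c(
                               "allowed" = 0.36, "banned" = 0.18,
                               "no specific law" = 0.39, "unknown" = 0.07
                             ),
                             baseline_prevalence = 0.015,
                             region_effects = c(
                               "African" = -0.8, "Eastern Mediterranean" = 0.3,
                               "European" = 0.1, "Americas" = 0.1,
                               "South-East Asia" = -1.0, "Western Pacific" = -0.1,
                               "unknown" = 0
                             ),
                             income_effects = c(
                               "high" = 0.35, "upper middle" = -0.1,
                               "lower middle" = -1.0, "low" = -1.0,
                               "unknown" = 0
                             ),
                             legal_effects = c(
                               "allowed" = 0.15, "banned" = -0.5,
                               "no specific law" = 0, "unknown" = 0
                             ),
                             noise_sd = 0.5,
                             pop_meanlog = c(
                               "high" = 15.6, "upper middle" = 16.3,
                               "lower middle" = 16.6, "low" = 16.2,
                               "unknown" = 14.0
                             ),
                             pop_sdlog = 1.6,
                             survey_probs = c(
                               "high" = 0.87, "upper middle" = 0.77,
                               "lower middle" = 0.09, "low" = 0.055,
                               "unknown" = 0.05
                             ),
                             survey_prob_pop_exponent = 0,
                             survey_noise_sd = 0,
                             survey_year_range = c(2012, 2019)) {
  check_marginal <- function(p, levels, lab) {
    if (!all(levels %in% names(p))) {
      abort(sprintf("`%s` must name every level: %s.", lab,
                    paste(levels, collapse = ", ")))
    }
    p <- p[levels]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("`%s` must be probabilities in [0, 1] summing to 1.", lab))
    }
    p
  }
  check_named <- function(x, levels, lab) {
    if (!all(levels %in% names(x))) {
      abort(sprintf("`%s` must name every level: %s.", lab,
                    paste(levels, collapse = ", ")))
    }
    x[levels]
  }
  if (n_countries < 1) abort("`n_countries` must be at least 1.")
  if (noise_sd < 0 || survey_noise_sd < 0) abort("Noise sd values must be >= 0.")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    abort("`baseline_prevalence` must lie strictly in (0, 1).")
  }
  structure(list(
    n_countries = as.integer(n_countries),
    region_probs = check_marginal(region_probs, factor_levels$who_region, "region_probs"),
    income_probs = check_marginal(income_probs, factor_levels$income_group, "income_probs"),
    legal_probs = check_marginal(legal_probs, factor_levels$legal_status, "legal_probs"),
    baseline_prevalence = baseline_prevalence,
    region_effects = check_named(region_effects, factor_levels$who_region, "region_effects"),
    income_effects = check_named(income_effects, factor_levels$income_group, "income_effects"),
    legal_effects = check_named(legal_effects, factor_levels$legal_status, "legal_effects"),
    noise_sd = noise_sd,
    pop_meanlog = check_named(pop_meanlog, factor_levels$income_group, "pop_meanlog"),
    pop_sdlog = pop_sdlog,
    survey_probs = {
      sp <- check_named(survey_probs, factor_levels$income_group, "survey_probs")
      if (any(sp < 0) || any(sp > 1)) abort("`survey_probs` must lie in [0, 1].")
      sp
    },
    survey_prob_pop_exponent = survey_prob_pop_exponent,
    survey_noise_sd = survey_noise_sd,
    survey_year_range = as.integer(survey_year_range)
  ), class = "synthetic_config")
}

# internal: deterministic synthetic 3-letter codes SAA, SAB, ... (S prefix
# keeps them visibly synthetic and clear of real ISO alpha-3 space for small n)
synthetic_iso3 <- function(n) {
  if (n > 26 * 26) abort("At most 676 synthetic countries are supported.")
  first <- LETTERS[((seq_len(n) - 1) %/% 26) + 1]
  second <- LETTERS[((seq_len(n) - 1) %% 26) + 1]
  paste0("S", first, second)
}

#' Generate a synthetic world with hidden ground truth
#'
#' Draws a country table from a [synthetic_config()]: factors from their
#' marginals, true prevalences from the logit-additive model, adult
#' populations from income-specific log-normals, and a survey mask from the
#' income-specific survey probabilities. The returned object pairs the
#' observed table (prevalence masked where unsurveyed) with the full truth,
#' enabling recovery experiments. Deterministic for a fixed seed
#' (Mersenne-Twister).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A `synthetic_world` list: `observed` (a world table whose
#'   `prevalence` is `NA` where unsurveyed), `truth` (tibble `iso3`,
#'   `true_prevalence`), `config`, `seed`.
#' @examples
#' sim <- generate_world(synthetic_config(n_countries = 30), seed = 1)
#' sum(!is.na(sim$observed$prevalence))
#' @export
generate_world <- function(config = synthetic_config(), seed = 1) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config().")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")

  n <- config$n_countries
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  region <- draw(config$region_probs)
  income <- draw(config$income_probs)
  legal <- draw(config$legal_probs)
  population <- rlnorm(n,
    meanlog = config$pop_meanlog[income],
    sdlog = config$pop_sdlog
  )
  logit_true <- qlogis(config$baseline_prevalence) +
    config$region_effects[region] +
    config$income_effects[income] +
    config$legal_effects[legal] +
    rnorm(n, 0, config$noise_sd)
  true_prevalence <- plogis(logit_true)

  prob <- config$survey_probs[income]
  if (config$survey_prob_pop_exponent != 0) {
    prob <- pmin(pmax(
      prob * (population / stats::median(population))^config$survey_prob_pop_exponent,
      0), 1)
  }
  surveyed <- unname(runif(n) < prob)
  observed_prev <- true_prevalence
  if (config$survey_noise_sd > 0) {
    observed_prev <- plogis(qlogis(true_prevalence) +
                              rnorm(n, 0, config$survey_noise_sd))
  }
  survey_year <- sample(
    seq(config$survey_year_range[1], config$survey_year_range[2]),
    n, replace = TRUE
  )

  iso3 <- synthetic_iso3(n)
  observed <- tibble::tibble(
    iso3 = iso3,
    name = paste("Synthetic country", seq_len(n)),
    who_region = unname(region),
    income_group = unname(income),
    legal_status = unname(legal),
    adult_population = round(unname(population)),
    prevalence = ifelse(surveyed, unname(observed_prev), NA_real_),
    survey_year = ifelse(surveyed, survey_year, NA_integer_)
  )
  structure(list(
    observed = validate_world_table(observed,
      survey_year_window = config$survey_year_range),
    truth = tibble::tibble(iso3 = iso3, true_prevalence = unname(true_prevalence)),
    config = config,
    seed = seed
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  n <- nrow(x$observed)
  ns <- sum(!is.na(x$observed$prevalence))
  cat("Synthetic world:", n, "countries,", ns, "surveyed (seed", x$seed, ")\n")
  cat("True world total:",
      format_count(sum(x$truth$true_prevalence * x$observed$adult_population)),
      "users\n")
  invisible(x)
}

#' Recovery experiment: how well does the cascade recover the truth?
#'
#' Repeatedly generates a synthetic world, imputes prevalences through the
#' cascade, aggregates to a world user total, and compares against the
#' hidden true total. Replicate `r` uses seed `seed + r`, so the whole
#' experiment is deterministic for a fixed seed. Besides total-level bias
#' and RMSE, it reports the mean absolute prevalence error at each cascade
#' level — observed countries (level 0) have zero error unless survey noise
#' is switched on, and error typically grows with level as subgroups
#' coarsen.
#'
#' @param config A [synthetic_config()].
#' @param n_reps Number of replicates (>= 1).
#' @param spec A [cascade_spec()].
#' @param seed Base seed.
#' @return A `recovery_experiment` list: `per_rep` (tibble with estimated
#'   and true world totals and errors per replicate), `per_level` (mean
#'   absolute prevalence error by cascade level, pooled over replicates),
#'   and `summary` (one row: `bias`, `relative_bias`, `rmse`,
#'   `relative_rmse`).
#' @examples
#' exp <- recovery_experiment(synthetic_config(n_countries = 40), n_reps = 5, seed = 7)
#' glance(exp)
#' @export
recovery_experiment <- function(config = synthetic_config(), n_reps = 100,
                                spec = cascade_spec(), seed = 1) {
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  reps <- purrr::map(seq_len(n_reps), function(r) {
    sim <- generate_world(config, seed = seed + r)
    fit <- cascade_impute(sim$observed, spec = spec)
    est_total <- aggregate_estimates(fit, sim$observed, by = "world")$n_vapers
    true_total <- sum(sim$truth$true_prevalence * sim$observed$adult_population)
    errors <- tibble::as_tibble(fit) |>
      dplyr::inner_join(sim$truth, by = "iso3") |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(
        abs_error = mean(abs(.data$prevalence - .data$true_prevalence)),
        n = dplyr::n(), .groups = "drop"
      )
    list(
      per_rep = tibble::tibble(
        rep = r, est_total = est_total, true_total = true_total,
        error = est_total - true_total,
        rel_error = (est_total - true_total) / true_total
      ),
      per_level = errors
    )
  })
  per_rep <- dplyr::bind_rows(purrr::map(reps, "per_rep"))
  per_level <- dplyr::bind_rows(purrr::map(reps, "per_level")) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      mean_abs_error = sum(.data$abs_error * .data$n) / sum(.data$n),
      n = sum(.data$n), .groups = "drop"
    )
  summary <- tibble::tibble(
    n_reps = n_reps,
    bias = mean(per_rep$error),
    relative_bias = mean(per_rep$error) / mean(per_rep$true_total),
    rmse = sqrt(mean(per_rep$error^2)),
    relative_rmse = sqrt(mean(per_rep$rel_error^2))
  )
  structure(list(per_rep = per_rep, per_level = per_level, summary = summary,
                 config = config, seed = seed),
            class = "recovery_experiment")
}

#' @describeIn recovery_experiment Per-replicate totals and errors.
#' @param x A `recovery_experiment` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.recovery_experiment <- function(x, ...) x$per_rep

#' @describeIn recovery_experiment One-row bias/RMSE summary.
#' @exportS3Method generics::glance
glance.recovery_experiment <- function(x, ...) x$summary

#' @export
print.recovery_experiment <- function(x, ...) {
  s <- x$summary
  cat("Recovery experiment:", s$n_reps, "replicates (seed", x$seed, ")\n")
  cat(sprintf("  relative bias of world total: %+.2f%%\n", 100 * s$relative_bias))
  cat(sprintf("  relative RMSE of world total: %.2f%%\n", 100 * s$relative_rmse))
  cat("  mean |prevalence error| by cascade level:\n")
  for (i in seq_len(nrow(x$per_level))) {
    cat(sprintf("    level %d: %.3f pp (n=%d)\n",
                x$per_level$level[i], 100 * x$per_level$mean_abs_error[i],
                x$per_level$n[i]))
  }
  invisible(x)
}

#' @describeIn recovery_experiment Mean absolute prevalence error per
#'   cascade level.
#' @param object A `recovery_experiment` object.
#' @exportS3Method ggplot2::autoplot
autoplot.recovery_experiment <- function(object, ...) {
  ggplot2::ggplot(object$per_level,
                  ggplot2::aes(factor(.data$level), 100 * .data$mean_abs_error)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(
      x = "cascade level (0 = observed)",
      y = "mean |prevalence error| (percentage points)",
      title = "Imputation error by cascade level"
    ) +
    ggplot2::theme_minimal()
}
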