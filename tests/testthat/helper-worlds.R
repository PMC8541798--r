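# Shared fixtures and the independent brute-force imputation oracle.

# Five-country toy world: two surveyed high/European/allowed countries at 2%
# and 4%, and three unsurveyed countries probing successively coarser cascade
# levels.
toy_world <- function() {
  tibble::tibble(
    iso3 = c("AAA", "BBB", "CCC", "DDD", "EEE"),
    name = paste("Country", 1:5),
    who_region = c("European", "European", "European", "Americas", "African"),
    income_group = c("high", "high", "high", "high", "low"),
    legal_status = c("allowed", "allowed", "allowed", "allowed", "banned"),
    adult_population = c(1e6, 2e6, 3e6, 4e6, 5e6),
    prevalence = c(0.02, 0.04, NA, NA, NA),
    survey_year = c(2017L, 2018L, NA, NA, NA)
  )
}

# Random world tables for property tests: factors drawn including "unknown",
# roughly half the countries surveyed (always at least one).
random_world <- function(n, p_survey = 0.5, p_unknown = 0.15) {
  pick <- function(levels) {
    known <- setdiff(levels, "unknown")
    ifelse(runif(n) < p_unknown, "unknown", sample(known, n, replace = TRUE))
  }
  surveyed <- runif(n) < p_survey
  if (!any(surveyed)) surveyed[sample.int(n, 1)] <- TRUE
  tibble::tibble(
    iso3 = prevcascade:::synthetic_iso3(n),
    name = paste("R", seq_len(n)),
    who_region = pick(factor_levels$who_region),
    income_group = pick(factor_levels$income_group),
    legal_status = pick(factor_levels$legal_status),
    adult_population = round(runif(n, 1e5, 1e9)),
    prevalence = ifelse(surveyed, runif(n, 0.002, 0.07), NA_real_),
    survey_year = ifelse(surveyed, sample(2012:2019, n, replace = TRUE), NA_integer_)
  )
}

# Independent reference: per country, scan the cascade and recompute each
# candidate group mean from scratch with base R. Returns iso3/prevalence/level.
brute_force_impute <- function(world, spec = cascade_spec(), min_group_n = 1) {
  surveyed <- world[!is.na(world$prevalence), ]
  out <- lapply(seq_len(nrow(world)), function(i) {
    row <- world[i, ]
    if (!is.na(row$prevalence)) {
      return(data.frame(iso3 = row$iso3, prevalence = row$prevalence, level = 0L))
    }
    for (lev in seq_along(spec)) {
      sig <- spec[[lev]]
      if (length(sig) == 0) {
        return(data.frame(iso3 = row$iso3,
                          prevalence = mean(surveyed$prevalence), level = lev))
      }
      if (any(unlist(row[sig]) == "unknown")) next
      keep <- rep(TRUE, nrow(surveyed))
      for (f in sig) {
        keep <- keep & surveyed[[f]] != "unknown" & surveyed[[f]] == row[[f]]
      }
      if (sum(keep) >= min_group_n) {
        return(data.frame(iso3 = row$iso3,
                          prevalence = mean(surveyed$prevalence[keep]),
                          level = lev))
      }
    }
    stop("brute-force oracle failed to assign a value")
  })
  res <- do.call(rbind, out)
  res[order(res$iso3), ]
}

# Write a world table to a temp CSV in the external (percent) convention.
write_world_csv <- function(world, path = tempfile(fileext = ".csv")) {
  write_country_table(world, path)
  path
}
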