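test_that("group statistics are unweighted means with sample sd, skipping unknown-factor countries", {
  three <- tibble::tibble(
    iso3 = c("AAA", "BBB", "CCC"),
    name = letters[1:3],
    who_region = "European",
    income_group = "high",
    legal_status = "allowed",
    adult_population = c(1e6, 1e6, 2e6),
    prevalence = c(0.01, 0.02, 0.03),
    survey_year = 2018L
  )
  stats <- compute_group_stats(three, "income_group")
  expect_equal(stats$mean_prevalence, 0.02)
  expect_equal(stats$n, 3L)
  expect_equal(stats$sd, 0.01)

  # population weighting is available but off by default
  weighted <- compute_group_stats(three, "income_group", weight_by_population = TRUE)
  expect_equal(weighted$mean_prevalence, 0.0225)

  single <- three[1, ]
  s <- compute_group_stats(single, "income_group")
  expect_equal(s$mean_prevalence, 0.01)
  expect_equal(s$n, 1L)
  expect_true(is.na(s$sd))

  unk <- dplyr::mutate(three, income_group = c("unknown", "high", "high"))
  expect_equal(compute_group_stats(unk, "income_group")$n, 2L)
})

test_that("goodness-of-fit interval follows mean +/- z*sd/sqrt(n) and degenerates honestly", {
  ci <- fit_interval(0.02, 0.01, 4, z = 1.96)
  expect_equal(ci$lower, 0.0102)
  expect_equal(ci$upper, 0.0298)

  expect_true(all(is.na(fit_interval(0.02, NA, 1))))
  deg <- fit_interval(0.02, 0, 10)
  expect_equal(deg$lower, 0.02)
  expect_equal(deg$upper, 0.02)
  # interval is truncated below at zero, never negative
  expect_equal(fit_interval(0.001, 0.05, 4)$lower, 0)
  expect_error(fit_interval(0.02, 0.01, 4, z = -1), "positive")
  expect_error(fit_interval(0.02, 0.01, 4, z = 0), "positive")
})

test_that("the five-country toy resolves to the hand-computed cascade levels", {
  fit <- cascade_impute(toy_world())
  get <- function(code) fit[fit$iso3 == code, ]
  # surveyed countries untouched at level 0
  expect_equal(get("AAA")$level, 0L)
  expect_identical(get("AAA")$prevalence, 0.02)
  expect_identical(get("BBB")$prevalence, 0.04)
  # full three-factor match
  expect_equal(get("CCC")$level, 1L)
  expect_equal(get("CCC")$prevalence, 0.03)
  # falls to income x legal
  expect_equal(get("DDD")$level, 2L)
  expect_equal(get("DDD")$prevalence, 0.03)
  # nothing matches until the global mean
  expect_equal(get("EEE")$level, 6L)
  expect_equal(get("EEE")$prevalence, 0.03)
  expect_equal(get("EEE")$group_key, "global")

  cov <- cascade_coverage(fit)
  expect_equal(cov$n_countries[cov$level %in% c(0, 1, 2, 6)], c(2L, 1L, 1L, 1L))
  expect_equal(cov$cumulative[nrow(cov)], 5L)
})

test_that("an all-surveyed world passes through unchanged at level 0", {
  world <- dplyr::mutate(random_world(15), prevalence = runif(15, 0.01, 0.05))
  fit <- cascade_impute(world)
  expect_true(all(fit$level == 0L))
  expect_identical(
    fit$prevalence,
    dplyr::arrange(world, iso3)$prevalence
  )
  cov <- cascade_coverage(fit)
  expect_equal(cov$n_countries[cov$level == 0], 15L)
})

test_that("a world with no surveys is a hard error", {
  world <- dplyr::mutate(toy_world(), prevalence = NA_real_, survey_year = NA_integer_)
  expect_error(cascade_impute(world), "[Nn]o surveyed")
})

test_that("cascade matches the brute-force oracle on random small tables", {
  set.seed(101)
  for (rep in 1:40) {
    world <- random_world(sample(3:20, 1))
    fit <- cascade_impute(world)
    ref <- brute_force_impute(world)
    expect_identical(fit$iso3, ref$iso3)
    expect_identical(fit$level, ref$level)
    expect_equal(fit$prevalence, ref$prevalence)
  }
})

test_that("cascade respects min_group_n, against the oracle", {
  set.seed(202)
  for (rep in 1:10) {
    world <- random_world(15)
    fit <- cascade_impute(world, min_group_n = 2)
    ref <- brute_force_impute(world, min_group_n = 2)
    expect_identical(fit$level, ref$level)
    expect_equal(fit$prevalence, ref$prevalence)
  }
})

test_that("cascade results are invariant to the input row order", {
  set.seed(303)
  world <- random_world(30)
  a <- cascade_impute(world)
  b <- cascade_impute(world[sample.int(nrow(world)), ])
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("every country gets a value whenever at least one survey exists", {
  set.seed(404)
  for (rep in 1:10) {
    world <- random_world(sample(2:40, 1), p_survey = 0.1)
    fit <- cascade_impute(world)
    expect_false(any(is.na(fit$prevalence)))
    expect_false(any(is.na(fit$level)))
  }
})

test_that("adding a survey never pushes another country to a worse cascade level", {
  set.seed(505)
  for (rep in 1:15) {
    world <- random_world(15, p_survey = 0.4)
    unsurveyed <- which(is.na(world$prevalence))
    if (length(unsurveyed) == 0) next
    before <- cascade_impute(world)
    pick <- sample(unsurveyed, 1)
    world2 <- world
    world2$prevalence[pick] <- runif(1, 0.005, 0.05)
    world2$survey_year[pick] <- 2018L
    after <- cascade_impute(world2)
    others <- setdiff(world$iso3, world$iso3[pick])
    lev_before <- before$level[match(others, before$iso3)]
    lev_after <- after$level[match(others, after$iso3)]
    expect_true(all(lev_after <= lev_before))
  }
})

test_that("imputation is exact when prevalence is a deterministic function of the level-1 key", {
  set.seed(606)
  # every combination present and surveyed at least once, no unknowns
  grid <- expand.grid(
    who_region = setdiff(factor_levels$who_region, "unknown"),
    income_group = setdiff(factor_levels$income_group, "unknown"),
    legal_status = setdiff(factor_levels$legal_status, "unknown"),
    stringsAsFactors = FALSE
  )
  key_prev <- runif(nrow(grid), 0.005, 0.06)
  world <- tibble::as_tibble(grid[rep(seq_len(nrow(grid)), 2), ])
  world$iso3 <- prevcascade:::synthetic_iso3(nrow(world))
  world$name <- world$iso3
  world$adult_population <- 1e6
  truth <- key_prev[rep(seq_len(nrow(grid)), 2)]
  # first copy surveyed, second copy masked
  world$prevalence <- c(key_prev, rep(NA_real_, nrow(grid)))
  world$survey_year <- c(rep(2018L, nrow(grid)), rep(NA_integer_, nrow(grid)))
  fit <- cascade_impute(world)
  expect_equal(fit$prevalence[match(world$iso3, fit$iso3)], truth)
})

test_that("cascade spec validation enforces a terminal global signature", {
  expect_error(cascade_spec(list("income_group")), "global")
  expect_error(cascade_spec(list(c("income_group", "income_group"), character(0))),
               "repeat")
  expect_error(cascade_spec(list("continent", character(0))), "Unknown factor")
  custom <- cascade_spec(list("who_region", character(0)))
  fit <- cascade_impute(toy_world(), spec = custom)
  expect_equal(max(fit$level), 2L)  # global is level 2 in this spec
})

test_that("provenance exports carry percent values and interval bounds", {
  fit <- cascade_impute(toy_world())
  path <- tempfile(fileext = ".csv")
  write_provenance(fit, path)
  prov <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(sort(prov$value_pct[prov$level == 0]), c(2, 4))
  td <- tidy(fit)
  expect_equal(td$value_pct, td$prevalence * 100)
  g <- glance(fit)
  expect_equal(g$n_observed + g$n_imputed, g$n_countries)
})
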