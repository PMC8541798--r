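test_that("generation is deterministic given a seed and differs across seeds", {
  cfg <- synthetic_config(n_countries = 50)
  a <- generate_world(cfg, seed = 42)
  b <- generate_world(cfg, seed = 42)
  expect_identical(a$observed, b$observed)
  expect_identical(a$truth, b$truth)
  c <- generate_world(cfg, seed = 43)
  expect_false(identical(a$truth$true_prevalence, c$truth$true_prevalence))
})

test_that("zero noise and zero effects yield exactly the baseline prevalence", {
  cfg <- synthetic_config(
    n_countries = 30,
    baseline_prevalence = 0.02,
    region_effects = setNames(rep(0, 7), factor_levels$who_region),
    income_effects = setNames(rep(0, 5), factor_levels$income_group),
    legal_effects = setNames(rep(0, 4), factor_levels$legal_status),
    noise_sd = 0
  )
  sim <- generate_world(cfg, seed = 5)
  expect_equal(sim$truth$true_prevalence, rep(0.02, 30))
})

test_that("true prevalences are strictly inside (0,1) and masking never alters truth", {
  sim <- generate_world(synthetic_config(n_countries = 120), seed = 9)
  expect_true(all(sim$truth$true_prevalence > 0 & sim$truth$true_prevalence < 1))
  obs <- sim$observed$prevalence
  truth <- sim$truth$true_prevalence[match(sim$observed$iso3, sim$truth$iso3)]
  expect_identical(obs[!is.na(obs)], truth[!is.na(obs)])
})

test_that("default coverage pattern puts the surveyed population share near half the world", {
  sim <- generate_world(synthetic_config(), seed = 1)
  share <- coverage_summary(sim$observed, "world")$surveyed_pct / 100
  expect_gt(share, 0.3)
  expect_lt(share, 0.7)
  # income gradient: high-income countries are surveyed far more often than low-income
  by_inc <- sim$observed |>
    dplyr::group_by(income_group) |>
    dplyr::summarise(rate = mean(!is.na(prevalence)))
  expect_gt(by_inc$rate[by_inc$income_group == "high"],
            by_inc$rate[by_inc$income_group == "low"])
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(income_probs = c(
    "high" = 0.5, "upper middle" = 0.2, "lower middle" = 0.2,
    "low" = 0.2, "unknown" = 0.1
  )), "summing to 1")
  expect_error(synthetic_config(noise_sd = -1), ">= 0")
  expect_error(synthetic_config(baseline_prevalence = 0), "\\(0, 1\\)")
  expect_error(synthetic_config(survey_probs = c(
    "high" = 2, "upper middle" = 0.5, "lower middle" = 0.5,
    "low" = 0.5, "unknown" = 0.5
  )), "\\[0, 1\\]")
})

zero_noise_config <- function(n = 40) {
  synthetic_config(
    n_countries = n,
    region_probs = c(
      "African" = 0.5, "Eastern Mediterranean" = 0, "European" = 0.5,
      "Americas" = 0, "South-East Asia" = 0, "Western Pacific" = 0, "unknown" = 0
    ),
    income_probs = c(
      "high" = 0.5, "upper middle" = 0, "lower middle" = 0, "low" = 0.5,
      "unknown" = 0
    ),
    legal_probs = c("allowed" = 0.5, "banned" = 0.5, "no specific law" = 0, "unknown" = 0),
    noise_sd = 0,
    survey_probs = c(
      "high" = 0.6, "upper middle" = 0.6, "lower middle" = 0.6, "low" = 0.6,
      "unknown" = 0.6
    )
  )
}

test_that("recovery is exact with zero within-group noise once every key is surveyed", {
  # with noise_sd 0, truth is a deterministic function of the three factors;
  # find a replicate where every level-1 key has a survey and expect zero error
  cfg <- zero_noise_config(60)
  exp1 <- recovery_experiment(cfg, n_reps = 5, seed = 3)
  sim_checks <- purrr::map_lgl(1:5, function(r) {
    sim <- generate_world(cfg, seed = 3 + r)
    obs <- sim$observed
    keys_all <- unique(paste(obs$who_region, obs$income_group, obs$legal_status))
    keys_surv <- unique(paste(obs$who_region, obs$income_group,
                              obs$legal_status)[!is.na(obs$prevalence)])
    all(keys_all %in% keys_surv)
  })
  covered <- which(sim_checks)
  expect_gt(length(covered), 0)
  expect_equal(exp1$per_rep$error[covered], rep(0, length(covered)))
})

test_that("full survey coverage recovers the true total exactly in every replicate", {
  cfg <- synthetic_config(
    n_countries = 50,
    survey_probs = c(
      "high" = 1, "upper middle" = 1, "lower middle" = 1, "low" = 1, "unknown" = 1
    )
  )
  exp <- recovery_experiment(cfg, n_reps = 5, seed = 11)
  expect_equal(exp$per_rep$error, rep(0, 5))
  expect_equal(exp$summary$rmse, 0)
  expect_equal(exp$summary$bias, 0)
})

test_that("raising survey probability drives total-recovery RMSE down", {
  rmse_at <- function(p) {
    cfg <- synthetic_config(
      n_countries = 100,
      survey_probs = c(
        "high" = p, "upper middle" = p, "lower middle" = p, "low" = p, "unknown" = p
      )
    )
    recovery_experiment(cfg, n_reps = 20, seed = 7)$summary$relative_rmse
  }
  r25 <- rmse_at(0.25)
  r50 <- rmse_at(0.5)
  r100 <- rmse_at(1.0)
  expect_gt(r25, r50)
  expect_gt(r50, r100)
  expect_equal(r100, 0)
})

test_that("the default world is overestimated, with bounded relative bias", {
  # survey availability tracks income, and income tracks prevalence, so the
  # cascade exports high-prevalence means into unsurveyed low-income
  # countries: the world total is biased upward
  exp <- recovery_experiment(synthetic_config(), n_reps = 100, seed = 7)
  expect_gt(exp$summary$relative_bias, 0)
  expect_lt(abs(exp$summary$relative_bias), 0.25)
})

test_that("the default-world experiment is summarised with tidy and glance", {
  exp <- recovery_experiment(synthetic_config(n_countries = 60), n_reps = 5, seed = 2)
  td <- tidy(exp)
  expect_equal(nrow(td), 5)
  g <- glance(exp)
  expect_named(g, c("n_reps", "bias", "relative_bias", "rmse", "relative_rmse"))
  expect_true(all(exp$per_level$level >= 0))
  # observed countries carry zero imputation error when surveys are noise-free
  expect_equal(exp$per_level$mean_abs_error[exp$per_level$level == 0], 0)
})
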