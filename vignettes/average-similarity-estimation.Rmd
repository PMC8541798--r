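---
title: "Estimating global e-cigarette use by average similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating global e-cigarette use by average similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevcascade)
```

## The estimation problem

Nationally representative surveys of current e-cigarette use (use at least
once in the last 30 days, among adults aged 15+) exist for only a minority
of countries, and their availability is strongly confounded with wealth:
most high-income populations are covered, almost no low-income populations
are. Any "global number of vapers" therefore rests on filling roughly three
quarters of the country list by assumption. `prevcascade` implements the
assumption most commonly used for this class of problem — *average
similarity*: countries sharing observable characteristics are taken to
share, on average, the unobserved prevalence.

The three characteristics used are the WHO region (six levels), the World
Bank income classification (four levels), and the legal status of
e-cigarette sale (allowed / banned / no specific law). Each factor also has
an explicit `"unknown"` level: a country with an unknown factor is an
ordinary record that simply cannot participate in subgroups requiring that
factor, and is reported in "Unknown" rows.

## The cascade

`cascade_impute()` walks an ordered list of factor signatures
(`cascade_spec()`), from most to least specific:

1. region × income × legal status
2. income × legal status
3. income × region
4. region × legal status
5. income
6. global mean over all surveyed countries

Within a signature, each subgroup's statistic is the *unweighted* arithmetic
mean of the observed prevalences of its surveyed countries — one country,
one value. Population weighting would let a single large surveyed country
dominate its stratum, which is not how the survey-count-based strata are
meant to work; it is nevertheless available behind
`weight_by_population = TRUE` for sensitivity analysis.

An unsurveyed country takes the mean of the first signature whose key (built
from the country's non-unknown factors) has at least `min_group_n` surveyed
countries. The default `min_group_n = 1` is deliberate: several strata rest
on a single survey (a whole region can be represented by one country), and
the method's premise is that a specific single-survey stratum is still more
informative than a coarser pooled one. Raising `min_group_n` trades that
specificity for stability. The terminal global level ignores the threshold,
so every country receives a value whenever at least one survey exists; a
table with no surveys at all is a hard error rather than a silent zero.

Provenance is first-class: every value carries its cascade level (0 =
observed) and subgroup key, `cascade_coverage()` reports the per-level and
cumulative coverage counts, and observed prevalences pass through bit-exact,
never recomputed.

### The goodness-of-fit interval

For a subgroup with `n ≥ 2` contributors the package attaches
`mean ± z·sd/√n`, truncated below at zero (prevalences cannot be negative),
with `sd` the sample (n−1) standard deviation. This is a deliberately
simplified interval: contributions are neither weighted nor
variance-stabilised, so it is a reliability flag, not a coverage-calibrated
confidence interval. At `n = 1` the sd is undefined and the interval is
reported as missing rather than as a fake zero-width band; at `sd = 0` the
interval honestly degenerates to a point. `z` defaults to 1.96 (a nominal
95% band) and is exposed because nothing in the method pins it down.

## From prevalence to people

User counts are prevalence × adult population, kept as real numbers
internally and rounded (half-up) to whole persons only in printed reports.
Aggregation over any partition — region, income, legal status, or the
surveyed/estimated split — conserves the un-rounded world total; the test
suite asserts conservation to a 10⁻¹² relative tolerance (the partitions sum
the same per-country terms in different orders, so the last few bits of an
IEEE double are not meaningful) and exactly at integer precision.
Percentages in coverage reports are rounded half-up to 2 decimal places;
half-up matches how the reference tables this layout mirrors were printed,
whereas base R's `round()` is half-to-even.

## Projection by market revenue

Survey years cluster several years behind the date one wants an estimate
for, so the world total is carried forward with the only broadly available
signal: e-cigarette market revenue, expressed as an index in percent of a
base year (default 2018) and calibrated so the base year maps to ratio 1.
Two readings of the revenue-to-users link are implemented because the
arithmetic is genuinely underdetermined:

* **index mode** (default): users scale in direct proportion to the
  calibrated ratio;
* **damped mode**: the *relative change* of the index is shrunk by the
  revenue–prevalence Pearson correlation ρ (default 0.933, a value
  estimated externally from a national series where both revenue and
  prevalence are observed over time; `pearson_correlation()` recomputes it
  for any user-supplied pair of series).

Index mode is the default because it reproduces the published headline this
pipeline is modelled on; damped mode is the most plausible reading of
"adjusting the series by the correlation coefficient". For a ρ in (0, 1)
the damped projection always lies between the base total and the index-mode
projection, and both modes return the base total exactly at the base year.
`run_project()` reports the two side by side rather than silently choosing
(for 2018→2020 with a 117% index the difference is ≈68.0 m vs ≈67.3 m).

## The synthetic world

`generate_world()` draws country tables with the statistical structure the
method assumes, plus the hidden truth, so that recovery experiments can
quantify how the estimator behaves when its assumptions hold, degrade, or
fail. The model:

* **Factors** are drawn independently from marginals approximating the real
  distribution of countries over regions, income classes and legal regimes,
  with ~1–7% "unknown" mass per factor.
* **True prevalence** is inverse-logit(baseline + region effect + income
  effect + legal effect + noise), with baseline 1.5% and effects chosen to
  reproduce the observed ordering (high income ≈ 2%, lower-middle/low
  ≈ 0.5%, bans depress use). The logit-additive form is the simplest model
  under which "similar countries have similar prevalence" is literally
  true; the country-level noise sd (default 0.5 on the log-odds scale)
  is the dial that controls how badly the similarity assumption fails.
* **Populations** are log-normal with income-group-specific locations
  (sdlog 1.6), spanning roughly 10⁵–10⁹ adults.
* **Survey availability** depends on income group only — probabilities
  {high 0.87, upper-middle 0.77, lower-middle 0.09, low 0.055} — the
  steep coverage gradient that drives the method's bias. A hook
  (`survey_prob_pop_exponent`) adds population-size dependence for
  sensitivity work. Surveys are noise-free by default (`survey_noise_sd`
  adds logit-scale measurement error when wanted).

Randomness uses R's Mersenne-Twister exclusively, seeded explicitly;
replicate *r* of an experiment uses `seed + r`, and generation restores the
caller's RNG state.

What the generator does *not* emulate: spatial or network correlation
between neighbouring countries, correlation between the three factors
(real income and region are far from independent), multiple surveys per
country, survey measurement bias, and time dynamics. Passing recovery tests
therefore show that the estimator is correct *under its own assumptions* —
they cannot show that real countries satisfy those assumptions.

### What the recovery experiments show

With zero within-group noise and every level-1 key surveyed, imputation
error is exactly zero — a structural identity the tests assert exactly, as
they do for full survey coverage. Under the default world, the estimated
world total is biased *upward* (relative bias on the order of +10–15%,
asserted below 25% at a fixed seed in the suite): survey availability tracks
income, income tracks prevalence, so the cascade exports high-prevalence
means into unsurveyed low-income countries. This reproduces, in a controlled
setting, the overestimation such estimates are suspected of in the real
world. RMSE of the recovered total falls monotonically as survey coverage
rises from 25% to 100%.

## Numerical and design choices

* Prevalence is stored as a fraction in [0, 1]; all file and report I/O
  uses percent (a file value of `7.1` is stored as 0.071).
* Validation is strict and front-loaded: duplicate ISO codes, negative
  populations, out-of-range prevalences, unrecognised factor labels and
  survey years outside the inclusion window (default 2012–2020) are hard
  errors naming the offending rows, raised before any computation.
* Results are sorted by ISO code, making every stage invariant to input
  row order; report CSVs are byte-identical across runs.
* Known limitation: published tables of this kind can carry internal
  inconsistencies (per-factor country counts that do not sum to the world
  count); the package always reports its own consistent counts and does not
  attempt to replicate such discrepancies.

## Problem sizes in the test suite

The suite validates the cascade against a brute-force per-country reference
on 500 random tables of up to 20 countries, conservation and coverage
properties on 201-country synthetic worlds, and recovery on experiments of
20–100 replicates; these sizes give stable assertions at sub-minute
runtimes while exercising every code path, and all scale linearly for users
who wish to rerun them larger.
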