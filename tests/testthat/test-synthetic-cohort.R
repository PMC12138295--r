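test_that("degenerate parameters collapse to the deterministic skeleton", {
  p <- generator_params(n_individuals = 6, n_weeks = 4, baseline_sd = 0,
                        nightly_sd_median = 0, nightly_sd_spread = 0,
                        weekend_effect_quartiles = c(0, 0, 0, 0),
                        weekend_effect_jitter_sd = 0, seasonal_drop = 0,
                        missingness_rate = 0, enrollment = "full", seed = 2)
  co <- generate_cohort(p)
  expect_true(all(co$hr == 61.375))
  expect_equal(nrow(co), 6 * 28)
})

test_that("identical parameters and seed give bit-identical cohorts", {
  p <- generator_params(n_individuals = 30, n_weeks = 10, seed = 9)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(ground_truth(a), ground_truth(b))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different cohort
  expect_false(identical(as.data.frame(generate_cohort(p, seed = 10)),
                         as.data.frame(a)))
})

test_that("unreachable heart-rate bounds abort instead of looping", {
  p <- generator_params(n_individuals = 4, n_weeks = 2, baseline_median = 150,
                        baseline_sd = 0, enrollment = "full", seed = 1)
  expect_error(generate_cohort(p), "resampling")
})

test_that("generated cohorts pass the inclusion filters without removals", {
  co <- generate_cohort(generator_params(n_individuals = 150, n_weeks = 20,
                                         seed = 13))
  reloaded <- as_cohort(co, week_start = attr(co, "week_start"))
  rep <- filter_report(reloaded)
  expect_equal(rep$removed_by_hr_bounds, character())
  expect_equal(rep$removed_by_week_validity, character())
  expect_equal(nrow(reloaded), nrow(co))
  expect_true(all(co$hr >= 30 & co$hr <= 100))
})

test_that("assigned-quartile weekend effects are recovered within 0.2 bpm", {
  co <- generate_cohort(generator_params(seed = 31)) # 2000 x 41 weeks
  gt <- ground_truth(co)
  mwe <- tapply(co$hr[co$is_weekend], co$participant_id[co$is_weekend], mean)
  mwd <- tapply(co$hr[!co$is_weekend], co$participant_id[!co$is_weekend], mean)
  d <- as.numeric(mwe[gt$participant_id] - mwd[gt$participant_id])
  observed <- tapply(d, gt$quartile, median) # Q1..Q4
  expected <- rev(generator_params()$weekend_effect_quartiles)
  expect_true(all(abs(observed - expected) < 0.2))
  # ground-truth effects center on the assigned quartile centers too
  latent <- tapply(gt$weekend_effect, gt$quartile, median)
  expect_true(all(abs(latent - expected) < 0.2))
})

test_that("observed stratification tracks the latent effect ranking", {
  # at full observation, rank-stratifying observed differences recovers
  # the quartile-of-latent-effect labels for most individuals (measurement
  # noise ~0.26 bpm against quartile-boundary mixture density)
  co <- generate_cohort(generator_params(seed = 37, enrollment = "full"))
  gt <- ground_truth(co)
  qs <- quartile_stratify(co)
  n <- nrow(gt)
  latent_rank_lab <- as.integer(cut(
    rank(gt$weekend_effect, ties.method = "first"),
    breaks = round(n * (0:4) / 4), include.lowest = TRUE
  ))
  obs <- qs$assignment$quartile[match(gt$participant_id,
                                      qs$assignment$participant_id)]
  expect_gte(mean(obs == latent_rank_lab), 0.80)
  # the top observed quartile is dominated by true top-quartile members
  expect_gte(mean(gt$quartile[obs == 4] == 4), 0.85)
})

test_that("the aggregate SD dominates the individual-SD distribution", {
  co <- generate_cohort(generator_params(n_individuals = 400, seed = 17,
                                         enrollment = "full"))
  an <- sd_analysis(co)
  expect_gte(an$percentile, 95)
})

test_that("the seasonal window medians recover the configured drop", {
  co <- generate_cohort(generator_params(n_individuals = 1000, seed = 19,
                                         enrollment = "full"))
  mon <- as.POSIXlt(co$night_date)$mon + 1
  drop <- median(co$hr[mon %in% 1:2]) - median(co$hr[mon %in% 3:4])
  expect_equal(drop, 0.75, tolerance = 0.25)
})

test_that("fixtures have their advertised structure", {
  const <- make_fixture("constant_effect", n_individuals = 3, n_weeks = 10)
  d <- tapply(const$hr[const$is_weekend],
              const$participant_id[const$is_weekend], mean) -
    tapply(const$hr[!const$is_weekend],
           const$participant_id[!const$is_weekend], mean)
  expect_true(all(d == 2))
  expect_equal(length(valid_weeks(const, "F01")), 10)

  null <- make_fixture("null_effect")
  expect_true(all(null$hr == 60))

  single <- make_fixture("single_week", n_individuals = 2)
  expect_equal(length(valid_weeks(single, "F01")), 1)

  sep <- make_fixture("separated_pools")
  expect_true(min(sep$hr[sep$is_weekend]) > max(sep$hr[!sep$is_weekend]))
  expect_false(anyDuplicated(sep$hr) > 0)

  expect_error(make_fixture("nope"))
})
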