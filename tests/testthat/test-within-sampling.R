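test_that("constant-effect individuals reach onset at 8 pairs in every run", {
  const <- make_fixture("constant_effect", n_individuals = 1, n_weeks = 10)
  for (mode in c("pooled", "temporal", "sequential")) {
    s <- run_within_individual(const, "F01", mode, n_runs = 20, seed = 5)
    expect_equal(s$n_significant_runs, 20)
    expect_true(all(s$runs$n_pairs_at_onset == 8))
    expect_equal(s$median_onset, 8)
    expect_equal(s$median_delta, 1)
    expect_equal(s$sign_class, "positive")
    expect_equal(s$n_valid_weeks, 10)
  }
})

test_that("null-effect individuals never reach significance", {
  null <- make_fixture("null_effect", n_individuals = 1, n_weeks = 12)
  s <- run_within_individual(null, "F01", "pooled", n_runs = 10, seed = 2)
  expect_equal(s$n_significant_runs, 0)
  expect_true(is.na(s$median_onset))
  expect_equal(s$sign_class, "censored")
})

test_that("fewer than 8 valid weeks cannot reach alpha = .01", {
  # the exact signed-rank floor is 2 * 2^-n; with 7 pairs the smallest
  # two-sided p is 2/128 > .01, so every run is censored
  const7 <- make_fixture("constant_effect", n_individuals = 1, n_weeks = 7)
  co <- generate_cohort(generator_params(n_individuals = 1, n_weeks = 7,
                                         missingness_rate = 0,
                                         enrollment = "full", seed = 3))
  for (cohort in list(const7, co)) {
    s <- run_within_individual(cohort, cohort$participant_id[1], "pooled",
                               n_runs = 25, seed = 7)
    expect_equal(s$n_significant_runs, 0)
  }
})

test_that("streams are capped at the number of valid weeks", {
  co <- generate_cohort(generator_params(n_individuals = 8, n_weeks = 9,
                                         seed = 21))
  for (pid in unique(co$participant_id)) {
    nv <- length(valid_weeks(co, pid))
    s <- run_within_individual(co, pid, "temporal", n_runs = 5, alpha = 1e-6,
                               seed = 3)
    # alpha so small that runs exhaust the stream: n_available == cap
    expect_equal(s$n_valid_weeks, nv)
    expect_true(all(is.na(s$runs$n_pairs_at_onset) |
                      s$runs$n_pairs_at_onset <= nv))
  }
})

test_that("single runs are reproducible in isolation", {
  co <- generate_cohort(generator_params(n_individuals = 5, n_weeks = 12,
                                         seed = 23))
  pid <- co$participant_id[1]
  a <- run_within_individual(co, pid, "temporal", n_runs = 10, seed = 99)
  b <- run_within_individual(co, pid, "temporal", n_runs = 10, seed = 99)
  expect_identical(a$runs, b$runs)
  expect_error(run_within_individual(co, "ghost", "pooled"), "unknown")
  expect_error(run_within_individual(co, pid, "modeX"))
})

test_that("aggregate_within separates symmetric positive/negative effects", {
  # half the participants +2 bpm on weekends, half -2: sign classes must be
  # symmetric with magnitudes equal by construction
  pos <- make_fixture("constant_effect", n_individuals = 4, n_weeks = 10)
  neg <- pos
  neg$hr <- ifelse(neg$is_weekend, 60, 62)
  neg$participant_id <- sub("F", "N", neg$participant_id)
  both <- rbind(as.data.frame(pos), as.data.frame(neg))
  co <- as_cohort(both)
  sw <- run_within_cohort(co, n_runs = 10, seed = 4)
  ag <- aggregate_within(sw)
  expect_equal(ag$n_individuals_kept, 8)
  pm <- ag$per_mode
  expect_equal(pm$n_positive, rep(4, 3))
  expect_equal(pm$n_negative, rep(4, 3))
  expect_equal(pm$median_delta_positive, -pm$median_delta_negative,
               tolerance = 1e-12)
  # constant-effect-only cohorts have a positive class only
  sw_pos <- run_within_cohort(pos, n_runs = 5, seed = 4)
  ag_pos <- aggregate_within(sw_pos)
  expect_equal(ag_pos$per_mode$n_negative, rep(0, 3))
  expect_equal(ag_pos$per_mode$n_neutral, rep(0, 3))
})

test_that("aggregation restricts to individuals significant in all modes", {
  # mix of strong-effect (10 weeks) and too-short (6 weeks) participants
  strong <- make_fixture("constant_effect", n_individuals = 2, n_weeks = 10)
  short <- make_fixture("constant_effect", n_individuals = 2, n_weeks = 6)
  short$participant_id <- sub("F", "S", short$participant_id)
  co <- as_cohort(rbind(as.data.frame(strong), as.data.frame(short)),
                  week_validity_mode = "lenient")
  sw <- run_within_cohort(co, n_runs = 5, seed = 1)
  ag <- aggregate_within(sw, restrict_to_all_modes_significant = TRUE)
  expect_equal(ag$n_individuals_total, 4)
  expect_equal(ag$n_individuals_kept, 2)
  unrestricted <- aggregate_within(sw, restrict_to_all_modes_significant = FALSE)
  expect_equal(unrestricted$n_individuals_kept, 4)
  # mismatched participant sets across modes are rejected
  broken <- sw[!(sw$mode == "pooled" & sw$participant_id == "F01"), ]
  expect_error(aggregate_within(broken), "same participants")
})

test_that("pooled and temporal modes draw from identical value multisets", {
  co <- generate_cohort(generator_params(n_individuals = 3, n_weeks = 12,
                                         seed = 25))
  pid <- co$participant_id[1]
  mine <- co[co$participant_id == pid, ]
  nv <- length(valid_weeks(co, pid))
  a <- run_within_individual(co, pid, "pooled", n_runs = 3, alpha = 1e-9,
                             seed = 5)
  # with unattainable alpha the run exhausts the stream; the sampled values
  # must be a subset of the participant's pools in every mode
  expect_true(all(a$runs$censored))
  expect_equal(a$n_valid_weeks, nv)
})

test_that("censoring is monotone in available weeks for constant effects", {
  # deterministic consequence of the discreteness floor: constant-effect
  # individuals are censored iff they have fewer than 8 valid weeks
  for (nw in c(5, 7, 8, 12)) {
    f <- make_fixture("constant_effect", n_individuals = 1, n_weeks = nw)
    s <- run_within_individual(f, "F01", "sequential", n_runs = 4, seed = 2)
    expect_equal(s$n_significant_runs, if (nw >= 8) 4 else 0)
  }
})
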