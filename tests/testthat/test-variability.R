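week0 <- as.Date("2020-01-06")

test_that("sd_analysis separates within- and between-individual spread", {
  # two individuals, two nights each (Thursday + Friday so the week is
  # valid), values {60,62} and {70,72}: equal individual SDs sqrt(2),
  # aggregate SD of the pooled four values
  nights <- week0 + 3:4
  df <- data.frame(
    participant_id = rep(c("a", "b"), each = 2),
    date = rep(nights, 2),
    hr = c(60, 62, 70, 72)
  )
  co <- load_nights(df, week_validity_mode = "lenient")
  an <- sd_analysis(co, window = range(nights))
  expect_equal(unname(an$individual_sds), rep(sqrt(2), 2))
  expect_equal(an$aggregate_sd, sd(c(60, 62, 70, 72)))
  expect_equal(an$percentile, 100)
  # constant individuals with distinct baselines: SDs 0, aggregate > 0
  df2 <- df; df2$hr <- rep(c(60, 70), each = 2)
  an2 <- sd_analysis(load_nights(df2, week_validity_mode = "lenient"),
                     window = range(nights))
  expect_equal(unname(an2$individual_sds), c(0, 0))
  expect_gt(an2$aggregate_sd, 0)
  expect_equal(an2$percentile, 100)
  # only individuals complete over the window enter: c misses the Friday
  df3 <- rbind(df, data.frame(participant_id = "c",
                              date = week0 + c(3, 10, 11), hr = 90))
  an3 <- sd_analysis(load_nights(df3, week_validity_mode = "lenient"),
                     window = range(nights))
  expect_equal(an3$n_complete, 2)
  expect_error(sd_analysis(co, window = c(week0 + 300, week0 + 301)),
               "complete")
})

test_that("nightly medians ignore missing values", {
  # a, b observed Mon+Tue+Fri; c observed Mon+Fri; d observed Sat+Sun
  df <- data.frame(
    participant_id = c(rep("a", 3), rep("b", 3), "c", "c", "d", "d"),
    date = c(week0 + c(0, 1, 4), week0 + c(0, 1, 4),
             week0 + c(0, 4), week0 + c(5, 6)),
    hr = c(60, 60, 60, 62, 62, 62, 64, 68, 66, 59)
  )
  co <- load_nights(df, week_validity_mode = "lenient")
  med <- nightly_median_series(co)
  expect_equal(med$median_hr[med$night_date == week0], 62)      # {60,62,64}
  expect_equal(med$median_hr[med$night_date == week0 + 1], 61)  # {60,62}
  expect_equal(med$median_hr[med$night_date == week0 + 6], 59)  # single value
  expect_equal(med$n[med$night_date == week0 + 1], 2L)
})

test_that("window_contrast reports medians, p and delta", {
  same <- window_contrast(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$delta, 0)
  shifted <- window_contrast(11:20 + 0.5, 1:10 + 0.4)
  expect_equal(shifted$delta, 1)
  expect_lt(shifted$p_two_sided, 0.01)
  expect_equal(shifted$median_a, median(11:20 + 0.5))
  paired <- window_contrast(c(2, 3, 4), c(1, 2, 3), paired = TRUE)
  expect_equal(paired$test, "wilcoxon_signed_rank")
})

test_that("quartile stratification matches the hand-worked example", {
  d <- c(-1, 0, 0.2, 0.4, 1, 1.3, 3, 4)
  df <- do.call(rbind, lapply(seq_along(d), function(i) {
    data.frame(participant_id = sprintf("p%02d", i),
               date = week0 + c(0, 4),          # Monday + Friday
               hr = c(60, 60 + d[i]))
  }))
  co <- load_nights(df, week_validity_mode = "lenient")
  qs <- quartile_stratify(co)
  q4 <- qs$assignment[qs$assignment$quartile == 4, ]
  expect_setequal(q4$participant_id, c("p07", "p08"))
  expect_equal(qs$quartile_summary$median[4], 3.5)
  expect_equal(qs$quartile_summary$n, rep(2, 4))
  # partition: every individual in exactly one quartile, near-equal sizes
  expect_equal(sort(table(qs$assignment$quartile)), sort(rep(2, 4)),
               ignore_attr = TRUE)
  # all differences equal -> all quartile medians equal
  df0 <- df; df0$hr <- rep(c(60, 61), length(d))
  qs0 <- quartile_stratify(load_nights(df0, week_validity_mode = "lenient"))
  expect_true(all(qs0$quartile_summary$median == 1))
  expect_error(quartile_stratify(load_nights(df[1:6, ],
                                             week_validity_mode = "lenient")),
               "at least 4")
})

test_that("quartile sizes differ by at most one on arbitrary cohorts", {
  set.seed(301)
  for (n in c(9, 14, 27)) {
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(participant_id = sprintf("p%02d", i),
                 date = week0 + c(0, 4), hr = c(60, 60 + rnorm(1)))
    }))
    qs <- quartile_stratify(load_nights(df, week_validity_mode = "lenient"))
    sizes <- table(qs$assignment$quartile)
    expect_lte(diff(range(sizes)), 1)
    # ranking respects the observed differences
    a <- qs$assignment
    expect_true(max(a$difference[a$quartile == 1]) <=
                  min(a$difference[a$quartile == 4]))
  }
})

test_that("time-delay embedding pairs nights exactly lag apart", {
  mk <- function(dates) load_nights(
    data.frame(participant_id = "a", date = dates,
               hr = 60 + seq_along(dates)),
    week_validity_mode = "lenient"
  )
  expect_equal(nrow(time_delay_embedding(mk(week0 + 0:6), lag = 7)), 0)
  one <- time_delay_embedding(mk(week0 + 0:7), lag = 7)
  expect_equal(nrow(one), 1)
  expect_equal(one$value_t, 61)
  expect_equal(one$value_lag, 68)
  expect_equal(one$night_type, "weekday") # Monday anchor
  # a gap at t + 7 produces no pair anchored at t
  gap <- time_delay_embedding(mk(week0 + c(0:6, 8:9)), lag = 7)
  expect_false(week0 %in% gap$night_date)
  expect_true((week0 + 1) %in% gap$night_date)
})
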