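make_df <- function(dates, hr = 60, pid = "a") {
  data.frame(participant_id = pid, date = as.Date(dates), hr = hr)
}

test_that("heart-rate bounds are strict and the boundary values are kept", {
  # two full weeks so the week-validity filter is not triggered
  dates <- as.Date("2020-01-06") + 0:13
  hr <- rep(60, 14)
  hr[1] <- 29.5   # below the lower bound -> removed
  hr[2] <- 30.0   # exactly on the bound -> retained
  hr[3] <- 100.0  # exactly on the bound -> retained
  hr[4] <- 100.5  # above -> removed
  co <- load_nights(make_df(dates, hr), week_validity_mode = "lenient")
  expect_equal(nrow(co), 12)
  expect_true(all(co$hr >= 30 & co$hr <= 100))
  expect_true(30 %in% co$hr && 100 %in% co$hr)
})

test_that("weekend labeling marks Friday and Saturday nights", {
  # 2020-01-10 is a Friday, 2020-01-09 a Thursday
  co <- load_nights(make_df(as.Date("2020-01-06") + 0:13))
  expect_true(co$is_weekend[co$night_date == as.Date("2020-01-10")])
  expect_false(co$is_weekend[co$night_date == as.Date("2020-01-09")])
  # independent day-of-week oracle across all of 2020
  year <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  co2 <- load_nights(make_df(year), week_validity_mode = "lenient")
  expected <- format(co2$night_date, "%u") %in% c("5", "6") # ISO Mon=1
  expect_equal(co2$is_weekend, expected)
})

test_that("malformed rows and duplicate nights are hard errors", {
  df <- make_df(as.Date("2020-01-06") + 0:6)
  bad_date <- df; bad_date$date <- as.character(bad_date$date)
  bad_date$date[3] <- "2020-13-40"
  expect_error(load_nights(bad_date), "row 3")
  bad_hr <- df; bad_hr$hr <- as.character(bad_hr$hr); bad_hr$hr[5] <- "sixty"
  expect_error(load_nights(bad_hr), "row 5")
  dup <- rbind(df, df[2, ])
  expect_error(load_nights(dup), "duplicate")
})

test_that("valid weeks require at least one weekend and one weekday night", {
  # week 0: Tue+Wed only (invalid); week 1: Fri+Mon (valid)
  dates <- as.Date(c("2020-01-07", "2020-01-08", "2020-01-13", "2020-01-17"))
  co <- load_nights(make_df(dates), week_validity_mode = "lenient")
  expect_equal(valid_weeks(co, "a"), 1L)
  expect_error(valid_weeks(co, "nobody"), "unknown participant")
  # fully observed weeks are all valid
  full <- load_nights(make_df(as.Date("2020-01-06") + 0:(41 * 7 - 1)))
  expect_equal(valid_weeks(full, "a"), 0:40)
})

test_that("strict mode drops participants with any invalid data-bearing week", {
  # participant a: 3 weeks, one weekday-only; participant b: all valid
  a <- make_df(c(as.Date("2020-01-06") + 0:6,          # week 0 full
                 as.Date("2020-01-14"),                # week 1 Tue only
                 as.Date("2020-01-20") + 0:6), pid = "a")
  b <- make_df(as.Date("2020-01-06") + 0:13, pid = "b")
  df <- rbind(a, b)
  strict <- load_nights(df, week_validity_mode = "strict")
  expect_setequal(unique(strict$participant_id), "b")
  lenient <- load_nights(df, week_validity_mode = "lenient")
  expect_setequal(unique(lenient$participant_id), c("a", "b"))
  expect_equal(length(valid_weeks(lenient, "a")), 2)
  rep <- filter_report(strict)
  expect_equal(rep$removed_by_week_validity, "a")
  # counts non-increasing along the chain
  expect_true(rep$n_participants_input >=
                rep$n_participants_after_hr_bounds)
  expect_true(rep$n_participants_after_hr_bounds >=
                rep$n_participants_after_week_validity)
})

test_that("an empty cohort passes through the validity rule unchanged", {
  co <- load_nights(make_df(as.Date("2020-01-06") + 0:13))
  empty <- co[0, ]
  class(empty) <- class(co)
  attr(empty, "week_start") <- attr(co, "week_start")
  expect_equal(nrow(apply_week_validity_rule(empty, "strict")), 0)
})

test_that("write/reload round-trips records and filtering is idempotent", {
  co <- generate_cohort(generator_params(n_individuals = 12, n_weeks = 8,
                                         seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  re <- load_nights(path, week_start = attr(co, "week_start"))
  expect_equal(re$participant_id, co$participant_id)
  expect_equal(re$night_date, co$night_date)
  expect_equal(re$hr, co$hr, tolerance = 1e-12)
  expect_equal(re$is_weekend, co$is_weekend)
  expect_equal(re$week_id, co$week_id)
  # applying the load-time filters again changes nothing
  again <- load_nights(path, week_start = attr(co, "week_start"))
  expect_equal(as.data.frame(again), as.data.frame(re))
  rep <- filter_report(again)
  expect_equal(rep$n_records_input, rep$n_records_after_week_validity)
})
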