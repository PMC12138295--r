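#' Nightly heart-rate cohorts
#'
#' A `night_cohort` is a data frame of participant-nights (one row per
#' participant per night) carrying the calendar conventions of the analysis:
#'
#' * `participant_id` -- opaque identifier,
#' * `night_date` -- the calendar date on which the sleep period began,
#' * `hr` -- mean sleeping heart rate for that night, in bpm,
#' * `is_weekend` -- `TRUE` iff the night began on a weekend night
#'   (Friday or Saturday by default),
#' * `week_id` -- 0-based calendar week, week 0 starting at the Monday on or
#'   before the study window start.
#'
#' Attributes record the week start date, the study window, the weekend-day
#' convention and the [filter_report()] of the load-time filters.
#'
#' @name night_cohort
NULL

.new_night_cohort <- function(df, week_start, weekend_days,
                              study_window = NULL, filter_report = NULL,
                              ground_truth = NULL, params = NULL) {
  df <- df[order(df$participant_id, df$night_date), , drop = FALSE]
  rownames(df) <- NULL
  out <- tibble::as_tibble(df)
  attr(out, "week_start") <- week_start
  attr(out, "weekend_days") <- weekend_days
  attr(out, "study_window") <- study_window %||%
    (if (nrow(df)) range(df$night_date) else as.Date(character()))
  attr(out, "filter_report") <- filter_report
  attr(out, "ground_truth") <- ground_truth
  attr(out, "generator_params") <- params
  class(out) <- c("night_cohort", class(tibble::tibble()))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.night_cohort <- function(x, ...) {
  win <- attr(x, "study_window")
  cat(sprintf(
    "<night_cohort> %d nights, %d participants, window %s .. %s\n",
    nrow(x), length(unique(x$participant_id)),
    as.character(win[1]), as.character(win[2])
  ))
  NextMethod()
}

#' Retrieve the load-time filter report of a cohort
#'
#' The report records, for each filtering stage (heart-rate bounds, week
#' validity), the participant and record counts before and after and the ids
#' of removed participants.  Counts are non-increasing along the chain.
#'
#' @param cohort a [night_cohort].
#' @return a list of class `filter_report`.
#' @export
filter_report <- function(cohort) {
  stopifnot(inherits(cohort, "night_cohort"))
  attr(cohort, "filter_report")
}

#' Ground truth of a synthetic cohort
#'
#' For cohorts produced by [generate_cohort()], the per-participant latent
#' parameters (baseline, nightly SD, true weekend effect, assigned weekend
#' effect quartile, entry week).  `NULL` for cohorts loaded from file.
#'
#' @param cohort a [night_cohort].
#' @return a tibble or `NULL`.
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "night_cohort"))
  attr(cohort, "ground_truth")
}

.make_filter_report <- function(n_participants_input, n_records_input,
                                after_hr, after_week,
                                removed_hr, removed_week) {
  structure(
    list(
      n_participants_input = n_participants_input,
      n_records_input = n_records_input,
      n_participants_after_hr_bounds = after_hr[["participants"]],
      n_records_after_hr_bounds = after_hr[["records"]],
      n_participants_after_week_validity = after_week[["participants"]],
      n_records_after_week_validity = after_week[["records"]],
      removed_by_hr_bounds = removed_hr,
      removed_by_week_validity = removed_week
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  input:               %d participants, %d records\n",
              x$n_participants_input, x$n_records_input))
  cat(sprintf("  after HR bounds:     %d participants, %d records\n",
              x$n_participants_after_hr_bounds, x$n_records_after_hr_bounds))
  cat(sprintf("  after week validity: %d participants, %d records\n",
              x$n_participants_after_week_validity,
              x$n_records_after_week_validity))
  invisible(x)
}

#' Load nightly heart-rate records and apply the inclusion filters
#'
#' Reads long-format nightly records (`participant_id,date,hr`, ISO-8601
#' dates, one row per participant-night), assigns weekend flags and calendar
#' weeks, and applies the two inclusion filters in order:
#'
#' 1. *Heart-rate bounds*: records with `hr` strictly below `hr_min` or
#'    strictly above `hr_max` are removed (the bounds themselves are kept).
#' 2. *Week validity*: see [apply_week_validity_rule()].  Under the default
#'    `"strict"` mode a participant is dropped if any week in which they have
#'    data lacks a weekend or a weekday night; `"lenient"` only requires at
#'    least one valid week.
#'
#' Weekend nights are nights beginning on Friday or Saturday; all other
#' nights are weekday nights.  Calendar weeks run Monday-Sunday; week 0
#' starts at the Monday on or before the earliest night (or `week_start`).
#'
#' @param source path to a CSV file, or a data frame with columns
#'   `participant_id`, `date`, `hr`.
#' @param hr_min,hr_max retained heart-rate range in bpm (inclusive).
#' @param weekend_days days whose nights count as weekend nights; day names
#'   or integers 0 (Sunday) to 6 (Saturday).
#' @param week_validity_mode `"strict"` or `"lenient"`.
#' @param week_start optional `Date`: the Monday anchoring week 0.
#' @return a [night_cohort]; retrieve the filter chain with
#'   [filter_report()].
#' @examples
#' df <- data.frame(
#'   participant_id = "a",
#'   date = as.Date("2020-01-06") + 0:13,
#'   hr = 60
#' )
#' cohort <- load_nights(df)
#' filter_report(cohort)
#' @export
load_nights <- function(source, hr_min = 30, hr_max = 100,
                        weekend_days = c("Friday", "Saturday"),
                        week_validity_mode = c("strict", "lenient"),
                        week_start = NULL) {
  week_validity_mode <- match.arg(week_validity_mode)
  wdays <- .day_numbers(weekend_days)
  df <- if (is.character(source)) {
    read.csv(source, colClasses = "character")
  } else {
    as.data.frame(source)
  }
  need <- c("participant_id", "date", "hr")
  if (!all(need %in% names(df))) {
    stop("input must have columns participant_id, date, hr", call. = FALSE)
  }
  pid <- as.character(df$participant_id)
  dates <- if (inherits(df$date, "Date")) df$date else
    as.Date(as.character(df$date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop(sprintf("malformed date at row %d: '%s'",
                 which(is.na(dates))[1], df$date[which(is.na(dates))[1]]),
         call. = FALSE)
  }
  hr <- if (is.numeric(df$hr)) as.numeric(df$hr) else
    suppressWarnings(as.numeric(df$hr))
  bad <- is.na(hr)
  if (any(bad)) {
    stop(sprintf("non-numeric hr at row %d: '%s'",
                 which(bad)[1], df$hr[which(bad)[1]]), call. = FALSE)
  }
  if (anyDuplicated(paste(pid, dates))) {
    d <- which(duplicated(paste(pid, dates)))[1]
    stop(sprintf("duplicate night for participant '%s' on %s (row %d)",
                 pid[d], as.character(dates[d]), d), call. = FALSE)
  }

  n_part_in <- length(unique(pid))
  n_rec_in <- length(pid)

  keep <- hr >= hr_min & hr <= hr_max
  removed_hr <- setdiff(unique(pid), unique(pid[keep]))
  pid <- pid[keep]; dates <- dates[keep]; hr <- hr[keep]

  week_start <- week_start %||%
    (if (length(dates)) .monday_on_or_before(min(dates)) else
       as.Date("2020-01-06"))
  if (.wday(week_start) != 1L) {
    stop("week_start must be a Monday", call. = FALSE)
  }

  df2 <- data.frame(
    participant_id = pid,
    night_date = dates,
    hr = hr,
    is_weekend = .wday(dates) %in% wdays,
    week_id = as.integer(floor(as.numeric(dates - week_start) / 7)),
    stringsAsFactors = FALSE
  )
  after_hr <- c(participants = length(unique(pid)), records = nrow(df2))

  cohort <- .new_night_cohort(df2, week_start, wdays)
  cohort <- apply_week_validity_rule(cohort, week_validity_mode)
  removed_week <- setdiff(unique(pid), unique(cohort$participant_id))
  after_week <- c(participants = length(unique(cohort$participant_id)),
                  records = nrow(cohort))

  attr(cohort, "filter_report") <- .make_filter_report(
    n_part_in, n_rec_in, after_hr, after_week, removed_hr, removed_week
  )
  cohort
}

#' Weeks with both a weekend and a weekday night for a participant
#'
#' A calendar week is *valid* for a participant when it contains at least one
#' weekend-night and one weekday-night record, so that a weekend/weekday pair
#' can be sampled from it.
#'
#' @param cohort a [night_cohort].
#' @param participant_id a participant present in the cohort.
#' @return an ascending integer vector of `week_id`s.
#' @export
valid_weeks <- function(cohort, participant_id) {
  stopifnot(inherits(cohort, "night_cohort"))
  rows <- cohort$participant_id == participant_id
  if (!any(rows)) {
    stop(sprintf("unknown participant '%s'", participant_id), call. = FALSE)
  }
  wk <- cohort$week_id[rows]
  we <- cohort$is_weekend[rows]
  sort(intersect(unique(wk[we]), unique(wk[!we])))
}

#' Apply the week-validity participant filter
#'
#' Two readings of the inclusion rule "at least one weekend night and one
#' weekday night per calendar week with data" are supported:
#'
#' * `"strict"`: drop a participant if *any* week in which they have data is
#'   invalid (the rule as a per-week requirement on every data-bearing week);
#' * `"lenient"`: drop a participant only if they have *no* valid week at
#'   all (invalid weeks coexist with valid ones and are simply never
#'   sampled).
#'
#' @param cohort a [night_cohort].
#' @param mode `"strict"` or `"lenient"`.
#' @return the filtered [night_cohort].
#' @export
apply_week_validity_rule <- function(cohort, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "night_cohort"))
  if (nrow(cohort) == 0) return(cohort)
  key <- paste(cohort$participant_id, cohort$week_id)
  has_we <- tapply(cohort$is_weekend, key, any)
  has_wd <- tapply(!cohort$is_weekend, key, any)
  valid <- has_we & has_wd
  pid_of_key <- sub(" [^ ]+$", "", names(valid))
  keep_pid <- if (mode == "strict") {
    names(which(tapply(valid, pid_of_key, all)))
  } else {
    names(which(tapply(valid, pid_of_key, any)))
  }
  out <- cohort[cohort$participant_id %in% keep_pid, , drop = FALSE]
  .new_night_cohort(
    as.data.frame(out), attr(cohort, "week_start"),
    attr(cohort, "weekend_days"), attr(cohort, "study_window"),
    attr(cohort, "filter_report"), attr(cohort, "ground_truth"),
    attr(cohort, "generator_params")
  )
}

#' Write a cohort back to the load format
#'
#' Writes `participant_id,date,hr` rows; reloading with [load_nights()] (same
#' options) reproduces the records exactly.
#'
#' @param cohort a [night_cohort].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "night_cohort"))
  write.csv(
    data.frame(
      participant_id = cohort$participant_id,
      date = as.character(cohort$night_date),
      hr = cohort$hr
    ),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
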