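#' Parameters of the synthetic nightly heart-rate generator
#'
#' The defaults are calibrated to the statistical structure of a large
#' wearable cohort observed over 41 Monday-anchored calendar weeks
#' (2020-01-06 to 2020-10-18):
#'
#' * `baseline_median = 61.375` bpm and `baseline_sd = 8.4` bpm reproduce the
#'   cohort weekday median and its interquartile spread (IQR about
#'   56.0-67.4 bpm, i.e. a normal SD of roughly 11.4/1.349);
#' * `nightly_sd_median = 2` bpm with log-scale spread `0.35` gives small
#'   within-individual night-to-night noise, so the aggregate population SD
#'   sits near the top of the individual-SD distribution;
#' * `weekend_effect_quartiles` are the quartile medians of the individual
#'   mean weekend-minus-weekday difference, supplied high to low
#'   (Q4, Q3, Q2, Q1), jittered per individual with
#'   `weekend_effect_jitter_sd`;
#' * `seasonal_drop = 0.75` bpm is the decline in median nightly HR from the
#'   January-February window to the March-April window, implemented as a
#'   linear per-night drift;
#' * `missingness_rate` is the per-night probability of an unobserved night;
#' * `enrollment = "staggered"` draws each participant's entry week uniformly
#'   over the study window, so weeks available range from 1 to `n_weeks`
#'   (as in rolling-enrollment cohorts); `"full"` observes everyone for the
#'   whole window.
#'
#' @param n_individuals number of participants.
#' @param n_weeks number of Monday-Sunday study weeks.
#' @param baseline_median,baseline_sd between-individual baseline
#'   distribution (normal), bpm.
#' @param nightly_sd_median,nightly_sd_spread within-individual nightly SD:
#'   log-normal with this median (bpm) and log-scale SD.
#' @param weekend_effect_quartiles quartile centers of the weekend effect in
#'   bpm, highest quartile first.
#' @param weekend_effect_jitter_sd SD of the per-individual jitter around the
#'   assigned quartile center, bpm.
#' @param seasonal_drop bpm decline between the Jan-Feb and Mar-Apr window
#'   medians.
#' @param missingness_rate per-night missingness probability in `[0, 1)`.
#' @param enrollment `"staggered"` or `"full"` (see Details).
#' @param week_start a Monday `Date` anchoring week 0.
#' @param hr_min,hr_max physiologic range; generated nights are kept inside
#'   it by resampling the nightly noise (rejection, not truncation).
#' @param seed default RNG seed used by [generate_cohort()].
#' @return a validated list of class `generator_params`.
#' @export
generator_params <- function(n_individuals = 2000,
                             n_weeks = 41,
                             baseline_median = 61.375,
                             baseline_sd = 8.4,
                             nightly_sd_median = 2.0,
                             nightly_sd_spread = 0.35,
                             weekend_effect_quartiles =
                               c(3.188, 1.250, 0.375, -0.500),
                             weekend_effect_jitter_sd = 0.75,
                             seasonal_drop = 0.75,
                             missingness_rate = 0.1,
                             enrollment = c("staggered", "full"),
                             week_start = as.Date("2020-01-06"),
                             hr_min = 30, hr_max = 100,
                             seed = 1L) {
  enrollment <- match.arg(enrollment)
  stopifnot(
    n_individuals >= 1, n_weeks >= 1,
    baseline_sd >= 0, nightly_sd_median >= 0, nightly_sd_spread >= 0,
    weekend_effect_jitter_sd >= 0,
    length(weekend_effect_quartiles) == 4,
    missingness_rate >= 0, missingness_rate < 1,
    hr_min < hr_max
  )
  if (.wday(week_start) != 1L) stop("week_start must be a Monday")
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_weeks = as.integer(n_weeks),
      baseline_median = baseline_median, baseline_sd = baseline_sd,
      nightly_sd_median = nightly_sd_median,
      nightly_sd_spread = nightly_sd_spread,
      weekend_effect_quartiles = as.numeric(weekend_effect_quartiles),
      weekend_effect_jitter_sd = weekend_effect_jitter_sd,
      seasonal_drop = seasonal_drop,
      missingness_rate = missingness_rate,
      enrollment = enrollment,
      week_start = week_start,
      hr_min = hr_min, hr_max = hr_max,
      seed = as.integer(seed)
    ),
    class = "generator_params"
  )
}

# Linear seasonal drift in bpm at night index t (0-based).  The slope is set
# so the median of the drift over Jan-Feb nights exceeds the median over
# Mar-Apr nights by `seasonal_drop`; the anchor night t* makes the
# attendance-weighted median drift zero, so the pooled cohort median stays at
# `baseline_median` under the enrollment model.
.seasonal_drift <- function(params) {
  nn <- params$n_weeks * 7L
  t <- seq_len(nn) - 1L
  mon <- as.POSIXlt(params$week_start + t)$mon + 1L # 1..12
  w <- if (params$enrollment == "staggered") {
    (t %/% 7L) + 1 # expected attendance grows linearly with entry spread
  } else {
    rep(1, nn)
  }
  wmed <- function(sel) {
    if (!any(sel)) return(NA_real_)
    ts <- t[sel]; ws <- w[sel]
    ts[which(cumsum(ws) >= sum(ws) / 2)[1]]
  }
  jf <- wmed(mon %in% c(1L, 2L))
  ma <- wmed(mon %in% c(3L, 4L))
  denom <- if (is.na(jf) || is.na(ma)) 58 else ma - jf
  m <- params$seasonal_drop / denom
  t_star <- t[which(cumsum(w) >= sum(w) / 2)[1]]
  m * (t_star - t)
}

#' Generate a synthetic nightly heart-rate cohort
#'
#' Simulates, for each participant *i*, a baseline `b_i ~ N(baseline_median,
#' baseline_sd^2)`, a nightly SD `s_i` (log-normal), and a weekend effect
#' `w_i = assigned quartile center + N(0, jitter^2)` (participants split
#' evenly across the four quartiles).  Each observed night *t* has
#'
#' `HR(i, t) = b_i + seasonal(t) + w_i * [weekend night] + N(0, s_i^2)`
#'
#' kept within `[hr_min, hr_max]` by resampling the nightly noise.  Nights
#' are dropped independently with probability `missingness_rate`, except that
#' a week which retains data is never allowed to lose all of its weekend (or
#' all of its weekday) nights to missingness alone -- one such night is
#' revived -- so a generated cohort always passes the week-validity filter
#' without removals.
#'
#' Identical parameters and seed give bit-identical cohorts.
#'
#' @param params a [generator_params()] list.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return a [night_cohort] whose [ground_truth()] attribute holds the
#'   per-participant latent parameters.
#' @examples
#' cohort <- generate_cohort(generator_params(n_individuals = 20,
#'                                            n_weeks = 6, seed = 7))
#' head(ground_truth(cohort))
#' @export
generate_cohort <- function(params = generator_params(), seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(seed %||% params$seed)
  n <- params$n_individuals
  nn <- params$n_weeks * 7L
  pid <- sprintf("S%05d", seq_len(n))

  quart <- rep(rep(1:4, length.out = 4L), length.out = n)
  quart <- sort(quart) # even split, Q1 = lowest effect center
  centers_low_to_high <- rev(params$weekend_effect_quartiles)
  baseline <- rnorm(n, params$baseline_median, params$baseline_sd)
  nightly_sd <- if (params$nightly_sd_median == 0) rep(0, n) else
    rlnorm(n, log(params$nightly_sd_median), params$nightly_sd_spread)
  effect <- centers_low_to_high[quart] +
    rnorm(n, 0, params$weekend_effect_jitter_sd)
  entry_week <- if (params$enrollment == "staggered") {
    sample.int(params$n_weeks, n, replace = TRUE) - 1L
  } else {
    rep(0L, n)
  }

  t <- seq_len(nn) - 1L
  dates <- params$week_start + t
  is_we_night <- .wday(dates) %in% c(5L, 6L)
  drift <- .seasonal_drift(params)

  idx_i <- rep(seq_len(n), each = nn)
  idx_t <- rep(t, times = n)
  keep <- idx_t >= 7L * entry_week[idx_i]
  idx_i <- idx_i[keep]; idx_t <- idx_t[keep]

  # iid missingness, then minimal repair so no data-bearing week loses an
  # entire weekend or weekday side
  miss <- runif(length(idx_i)) < params$missingness_rate
  if (any(miss)) {
    wk <- idx_t %/% 7L
    key <- (idx_i - 1L) * params$n_weeks + wk + 1L
    we <- is_we_night[idx_t + 1L]
    nb <- n * params$n_weeks
    kept_we <- tabulate(key[!miss & we], nbins = nb)
    kept_wd <- tabulate(key[!miss & !we], nbins = nb)
    revive_side <- function(side_dropped, kept_this, kept_other) {
      cand <- which(side_dropped)
      cand_key <- key[cand]
      need <- kept_this[cand_key] == 0L & kept_other[cand_key] > 0L
      cand <- cand[need]
      cand[!duplicated(key[cand])] # one revived night per starved week
    }
    miss[revive_side(miss & we, kept_we, kept_wd)] <- FALSE
    miss[revive_side(miss & !we, kept_wd, kept_we)] <- FALSE
    idx_i <- idx_i[!miss]; idx_t <- idx_t[!miss]
  }

  we_row <- is_we_night[idx_t + 1L]
  det <- baseline[idx_i] + drift[idx_t + 1L] + effect[idx_i] * we_row
  sds <- nightly_sd[idx_i]
  lo <- params$hr_min; hi <- params$hr_max
  if (any(det < lo - 6 * sds | det > hi + 6 * sds)) {
    stop("baseline/effect combination places nights too far outside ",
         "[hr_min, hr_max]; bounded resampling would not terminate",
         call. = FALSE)
  }
  hr <- det + rnorm(length(det), 0, sds)
  for (iter in seq_len(1000L)) {
    out <- which(hr < lo | hr > hi)
    if (!length(out)) break
    hr[out] <- det[out] + rnorm(length(out), 0, sds[out])
  }
  if (any(hr < lo | hr > hi)) {
    stop("bounded resampling failed to converge", call. = FALSE)
  }

  truth <- tibble::tibble(
    participant_id = pid,
    baseline = baseline,
    nightly_sd = nightly_sd,
    weekend_effect = effect,
    quartile = quart,
    entry_week = entry_week,
    n_weeks_observed = params$n_weeks - entry_week
  )

  df <- data.frame(
    participant_id = pid[idx_i],
    night_date = dates[idx_t + 1L],
    hr = hr,
    is_weekend = we_row,
    week_id = idx_t %/% 7L,
    stringsAsFactors = FALSE
  )
  .new_night_cohort(
    df, params$week_start, c(5L, 6L),
    study_window = c(dates[1], dates[nn]),
    filter_report = .make_filter_report(
      n, length(hr),
      c(participants = n, records = length(hr)),
      c(participants = n, records = length(hr)),
      character(), character()
    ),
    ground_truth = truth, params = params
  )
}

#' Tiny deterministic oracle cohorts
#'
#' Hand-constructed cohorts with known answers, used as test inputs:
#'
#' * `constant_effect`: every weekday night is exactly 60 bpm and every
#'   weekend night exactly 62 bpm, all nights observed -- every
#'   weekend-minus-weekday difference is +2 bpm;
#' * `null_effect`: every night is 60 bpm -- weekend and weekday
#'   distributions are identical and all paired differences are zero;
#' * `single_week`: each participant has exactly one valid week (one Friday
#'   and one Monday night);
#' * `separated_pools`: all weekend values lie strictly above all weekday
#'   values, and all values are distinct (complete separation without ties).
#'
#' @param kind one of `"constant_effect"`, `"null_effect"`, `"single_week"`,
#'   `"separated_pools"`.
#' @param n_individuals,n_weeks cohort size.
#' @return a [night_cohort].
#' @export
make_fixture <- function(kind = c("constant_effect", "null_effect",
                                  "single_week", "separated_pools"),
                         n_individuals = 4, n_weeks = 10) {
  kind <- match.arg(kind)
  week_start <- as.Date("2020-01-06")
  pid <- sprintf("F%02d", seq_len(n_individuals))
  if (kind == "single_week") {
    rows <- expand.grid(p = seq_len(n_individuals), d = c(0L, 4L))
    df <- data.frame(
      participant_id = pid[rows$p],
      night_date = week_start + rows$d, # Monday and Friday of week 0
      hr = ifelse(rows$d == 4L, 62, 60)
    )
  } else {
    t <- seq_len(n_weeks * 7L) - 1L
    dates <- week_start + t
    we <- .wday(dates) %in% c(5L, 6L)
    rows <- expand.grid(p = seq_len(n_individuals), t = t)
    wrow <- we[rows$t + 1L]
    hr <- switch(kind,
      constant_effect = ifelse(wrow, 62, 60),
      null_effect = rep(60, nrow(rows)),
      # incommensurable spacings keep every value AND every weekend-weekday
      # difference distinct, so exact small-sample nulls always apply
      separated_pools = ifelse(
        wrow,
        70 + 0.001 * (rows$t + n_weeks * 7L * rows$p),
        50 + 0.001 * sqrt(2) * (rows$t + n_weeks * 7L * rows$p)
      )
    )
    df <- data.frame(
      participant_id = pid[rows$p],
      night_date = dates[rows$t + 1L],
      hr = hr
    )
  }
  df$is_weekend <- .wday(df$night_date) %in% c(5L, 6L)
  df$week_id <- as.integer(floor(as.numeric(df$night_date - week_start) / 7))
  .new_night_cohort(df, week_start, c(5L, 6L))
}
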