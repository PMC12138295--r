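#' Individual versus aggregate heart-rate variability in a window
#'
#' For a calendar window, keeps only individuals with *complete* data (a
#' record on every night of the window), computes each one's SD of nightly
#' heart rate, the aggregate SD over the pooled values of those same
#' individuals, and the percentile rank of the aggregate SD within the
#' individual-SD distribution.  In cohorts whose between-individual baseline
#' spread dominates nightly noise the aggregate SD sits near the top of the
#' individual-SD distribution.
#'
#' @param cohort a [night_cohort].
#' @param window `Date` vector of length 2 (first and last night,
#'   inclusive); defaults to May 2020.
#' @return a list with `individual_sds` (named), `aggregate_sd`,
#'   `percentile` (0-100), `n_complete`, `window`.
#' @export
sd_analysis <- function(cohort,
                        window = as.Date(c("2020-05-01", "2020-05-31"))) {
  stopifnot(inherits(cohort, "night_cohort"), length(window) == 2)
  nights <- seq(window[1], window[2], by = "day")
  sel <- cohort$night_date >= window[1] & cohort$night_date <= window[2]
  sub <- cohort[sel, , drop = FALSE]
  cnt <- table(sub$participant_id)
  complete <- names(cnt)[cnt == length(nights)]
  if (length(complete) == 0) {
    stop("no individual has complete data in the window", call. = FALSE)
  }
  sub <- sub[sub$participant_id %in% complete, , drop = FALSE]
  ind <- c(tapply(sub$hr, sub$participant_id, sd)) # plain named vector
  agg <- sd(sub$hr)
  list(
    individual_sds = ind,
    aggregate_sd = agg,
    percentile = 100 * mean(ind <= agg),
    n_complete = length(complete),
    window = window
  )
}

#' Median nightly heart rate across the cohort
#'
#' For each study night, the median over the participants with a value that
#' night; missing nights contribute nothing (no imputation).
#'
#' @param cohort a [night_cohort].
#' @return a tibble with `night_date`, `median_hr`, `n` (values that night).
#' @export
nightly_median_series <- function(cohort) {
  stopifnot(inherits(cohort, "night_cohort"), nrow(cohort) > 0)
  med <- tapply(cohort$hr, cohort$night_date, median)
  n <- tapply(cohort$hr, cohort$night_date, length)
  tibble::tibble(
    night_date = as.Date(names(med)),
    median_hr = as.numeric(med),
    n = as.integer(n)
  )
}

#' Contrast two sets of heart-rate values
#'
#' Medians and IQRs of each set, a two-sided Mann-Whitney U (or Wilcoxon
#' signed-rank when `paired = TRUE`) p-value, and Cliff's delta with the
#' first set as the first sample (positive delta: first set stochastically
#' larger).  Used for the seasonal (Jan-Feb vs Mar-Apr) and weekend/weekday
#' contrasts.
#'
#' @param values_a,values_b non-empty numeric vectors (equal length when
#'   `paired = TRUE`).
#' @param paired whether values are matched one-to-one.
#' @return a list with `median_a`, `iqr_a`, `median_b`, `iqr_b`,
#'   `p_two_sided`, `delta`, `test`.
#' @export
window_contrast <- function(values_a, values_b, paired = FALSE) {
  .check_sample(values_a, "values_a"); .check_sample(values_b, "values_b")
  t <- if (paired) {
    stopifnot(length(values_a) == length(values_b))
    wilcoxon_signed_rank(values_a - values_b)
  } else {
    mann_whitney_u(values_a, values_b)
  }
  list(
    median_a = median(values_a), iqr_a = .iqr_bounds(values_a),
    median_b = median(values_b), iqr_b = .iqr_bounds(values_b),
    p_two_sided = t$p_two_sided,
    delta = cliffs_delta(values_a, values_b),
    test = t$test
  )
}

# pooled HR values whose night falls in the given months (1..12)
.month_values <- function(cohort, months) {
  cohort$hr[(as.POSIXlt(cohort$night_date)$mon + 1L) %in% months]
}

#' Stratify individuals into quartiles of their weekend effect
#'
#' Each individual's signed difference `d_i = mean(weekend HR) -
#' mean(weekday HR)` over all their available data is computed; individuals
#' are ranked by `d_i` (ties broken by participant id) and cut into four
#' groups of near-equal size: Q1 holds the lowest differences, Q4 the
#' highest.  Pairwise Mann-Whitney U tests compare the `d_i` distributions
#' between all quartile pairs.
#'
#' The stratification uses the *signed* difference: the lowest quartile of a
#' heterogeneous cohort typically has a negative median (higher weekday than
#' weekend heart rate), which an absolute-value reading would hide.
#'
#' @param cohort a [night_cohort] in which every individual has at least one
#'   weekend and one weekday value.
#' @return a list with `assignment` (tibble: `participant_id`, `difference`,
#'   `quartile`), `quartile_summary` (tibble: `quartile`, `n`, `median`,
#'   `q1`, `q3`), and `pairwise_p` (4x4 matrix of two-sided Mann-Whitney U
#'   p-values).
#' @export
quartile_stratify <- function(cohort) {
  stopifnot(inherits(cohort, "night_cohort"))
  mwe <- tapply(cohort$hr[cohort$is_weekend],
                cohort$participant_id[cohort$is_weekend], mean)
  mwd <- tapply(cohort$hr[!cohort$is_weekend],
                cohort$participant_id[!cohort$is_weekend], mean)
  pids <- sort(unique(cohort$participant_id))
  if (!all(pids %in% names(mwe)) || !all(pids %in% names(mwd))) {
    stop("every individual needs at least one weekend and one weekday value",
         call. = FALSE)
  }
  d <- as.numeric(mwe[pids] - mwd[pids])
  n <- length(d)
  if (n < 4) stop("need at least 4 individuals", call. = FALSE)
  ord <- order(d, pids)
  bounds <- round(n * (1:4) / 4)
  q <- integer(n)
  q[ord] <- rep(1:4, times = diff(c(0L, bounds)))
  assignment <- tibble::tibble(participant_id = pids, difference = d,
                               quartile = q)
  qs <- do.call(rbind, lapply(1:4, function(k) {
    v <- d[q == k]
    b <- .iqr_bounds(v)
    data.frame(quartile = k, n = length(v), median = median(v),
               q1 = b[1], q3 = b[2])
  }))
  pw <- matrix(NA_real_, 4, 4, dimnames = list(paste0("Q", 1:4),
                                               paste0("Q", 1:4)))
  for (a in 1:3) {
    for (b in (a + 1):4) {
      pw[a, b] <- pw[b, a] <-
        mann_whitney_u(d[q == a], d[q == b])$p_two_sided
    }
  }
  list(assignment = assignment, quartile_summary = tibble::as_tibble(qs),
       pairwise_p = pw)
}

#' Time-delay embedding of nightly heart-rate series
#'
#' Pairs every same-individual value with the value exactly `lag` nights
#' later; a missing night at either end produces no pair.  Each pair is
#' labelled with the night type (weekend/weekday) of the anchor night,
#' which at `lag = 7` exposes the weekly rhythm as separated clusters.
#'
#' @param cohort a [night_cohort].
#' @param lag lag in nights (>= 1); default 7.
#' @param participants optional subset of participant ids.
#' @return a tibble with `participant_id`, `night_date` (anchor `t`),
#'   `value_t`, `value_lag` (value at `t + lag`), `night_type` of `t`.
#' @export
time_delay_embedding <- function(cohort, lag = 7, participants = NULL) {
  stopifnot(inherits(cohort, "night_cohort"), lag >= 1)
  sub <- if (is.null(participants)) cohort else
    cohort[cohort$participant_id %in% participants, , drop = FALSE]
  key <- paste(sub$participant_id, sub$night_date)
  target <- paste(sub$participant_id, sub$night_date + lag)
  j <- match(target, key)
  ok <- !is.na(j)
  tibble::tibble(
    participant_id = sub$participant_id[ok],
    night_date = sub$night_date[ok],
    value_t = sub$hr[ok],
    value_lag = sub$hr[j[ok]],
    night_type = ifelse(sub$is_weekend[ok], "weekend", "weekday")
  )
}
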