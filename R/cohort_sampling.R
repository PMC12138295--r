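#' Build one cohort-wide dataset of weekend/weekday pairs
#'
#' For each participant, a calendar week is drawn uniformly from their valid
#' weeks, then one weekend-night and one weekday-night heart-rate value are
#' drawn uniformly from that week, giving exactly one pair per participant.
#' The participant order of the resulting dataset is randomized once.
#'
#' @param cohort a [night_cohort] (every participant must have at least one
#'   valid week, which the load-time filters guarantee).
#' @param seed optional RNG seed for this dataset.
#' @return a tibble with columns `participant_id`, `week_id`, `weekend_hr`,
#'   `weekday_hr`; one row per participant.
#' @export
build_cohort_dataset <- function(cohort, seed = NULL) {
  frame <- .frame_of(cohort)
  if (!is.null(seed)) set.seed(seed)
  if (any(frame$vw_len == 0L)) {
    stop(sprintf("participant '%s' has no valid week (cohort not filtered?)",
                 frame$pid[which(frame$vw_len == 0L)[1]]), call. = FALSE)
  }
  n <- frame$n
  wk <- frame$vw_flat[frame$vw_off + .runif_index(frame$vw_len)]
  ij <- cbind(seq_len(n), wk + 1L)
  we <- frame$we$vals[frame$we$off[ij] + .runif_index(frame$we$len[ij])]
  wd <- frame$wd$vals[frame$wd$off[ij] + .runif_index(frame$wd$len[ij])]
  perm <- sample.int(n)
  tibble::tibble(
    participant_id = frame$pid[perm],
    week_id = wk[perm],
    weekend_hr = we[perm],
    weekday_hr = wd[perm]
  )
}

#' Scramble a cohort-wide dataset into one of the four sampling designs
#'
#' Starting from a dataset built by [build_cohort_dataset()] (pairs matched
#' by individual *and* calendar week), each design breaks or keeps parts of
#' the pairing structure and dictates the test applied downstream:
#'
#' * `random`: weekend and weekday values independently permuted across all
#'   pairs; nothing is matched; unpaired test (Mann-Whitney U).
#' * `temporal`: weekend values permuted only among pairs sharing a calendar
#'   week (weekday side held), so pairs stay matched by week but not by
#'   individual; paired test (Wilcoxon signed-rank).
#' * `person_matched`: for each participant, weekend and weekday values are
#'   re-drawn independently from that participant's pools across *all* their
#'   weeks; matched by individual but not by week; paired test.
#' * `temporal_person_matched`: the dataset unchanged -- matched by both
#'   individual and week; paired test.
#'
#' Every design preserves the multisets of weekend and of weekday values.
#'
#' @param dataset a tibble from [build_cohort_dataset()].
#' @param method one of the four designs.
#' @param frame the cohort (or its internal frame) the dataset was built
#'   from; required for `person_matched`.
#' @param seed optional RNG seed.
#' @return a list with `pairs` (tibble in stream order), `test`
#'   (`"unpaired"` or `"paired"`) and `method`.
#' @export
scramble_pairs <- function(dataset,
                           method = c("random", "temporal", "person_matched",
                                      "temporal_person_matched"),
                           frame = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset)
  pairs <- switch(method,
    random = tibble::tibble(
      participant_id = NA_character_, week_id = NA_integer_,
      weekend_hr = sample(dataset$weekend_hr),
      weekday_hr = sample(dataset$weekday_hr)
    ),
    temporal = {
      we <- dataset$weekend_hr
      for (g in split(seq_len(n), dataset$week_id)) {
        we[g] <- we[g[sample.int(length(g))]]
      }
      tibble::tibble(
        participant_id = NA_character_, week_id = dataset$week_id,
        weekend_hr = we, weekday_hr = dataset$weekday_hr
      )
    },
    person_matched = {
      fr <- .frame_of(frame %||%
        stop("person_matched scrambling needs the cohort (frame =)",
             call. = FALSE))
      i <- match(dataset$participant_id, fr$pid)
      we <- fr$we$vals[fr$we$pool_off[i] + .runif_index(fr$we$pool_len[i])]
      wd <- fr$wd$vals[fr$wd$pool_off[i] + .runif_index(fr$wd$pool_len[i])]
      tibble::tibble(
        participant_id = dataset$participant_id, week_id = NA_integer_,
        weekend_hr = we, weekday_hr = wd
      )
    },
    temporal_person_matched = dataset
  )
  list(
    pairs = pairs,
    test = if (method == "random") "unpaired" else "paired",
    method = method
  )
}

#' Run the four cohort-wide sampling designs over replicated datasets
#'
#' Each run builds a fresh cohort-wide dataset (one weekend/weekday pair per
#' participant) from a run-specific seed derived from `seed`, applies each
#' design's scramble, and feeds the resulting stream to [find_onset()].
#'
#' @param cohort a [night_cohort].
#' @param n_runs number of replicated datasets.
#' @param alpha two-sided significance threshold.
#' @param seed master seed.
#' @param methods subset of the four designs.
#' @return an object of class `cohort_method_runs`: a list with `runs` (one
#'   row per method x run: onset, p and Cliff's delta at onset, censoring)
#'   and `summary` (per-method medians and IQRs over non-censored runs, and
#'   censoring counts).
#' @export
run_cohort_methods <- function(cohort, n_runs = 100, alpha = 0.01, seed = 1,
                               methods = c("random", "temporal",
                                           "person_matched",
                                           "temporal_person_matched")) {
  stopifnot(n_runs >= 1)
  .assert_prob(alpha, "alpha")
  methods <- match.arg(methods, several.ok = TRUE)
  frame <- .frame_of(cohort)
  rows <- vector("list", n_runs * length(methods))
  k <- 0L
  for (r in seq_len(n_runs)) {
    set.seed(.derive_seed(seed, "cohort_dataset", r))
    dataset <- build_cohort_dataset(frame)
    for (m in methods) {
      set.seed(.derive_seed(seed, "scramble", m, r))
      sc <- scramble_pairs(dataset, m, frame = frame)
      on <- find_onset(sc$pairs, test = sc$test, alpha = alpha)
      k <- k + 1L
      rows[[k]] <- data.frame(
        method = m, run = r,
        n_pairs_at_onset = on$n_pairs_at_onset %||% NA_integer_,
        p_at_onset = on$p_at_onset %||% NA_real_,
        delta_at_onset = on$delta_at_onset %||% NA_real_,
        censored = on$censored, n_available = on$n_available
      )
    }
  }
  runs <- tibble::as_tibble(do.call(rbind, rows))
  summary <- do.call(rbind, lapply(split(runs, runs$method), function(d) {
    sig <- d[!d$censored, , drop = FALSE]
    onset_iqr <- .iqr_bounds(sig$n_pairs_at_onset)
    delta_iqr <- .iqr_bounds(sig$delta_at_onset)
    data.frame(
      method = d$method[1], n_runs = nrow(d), n_censored = sum(d$censored),
      median_onset = if (nrow(sig)) median(sig$n_pairs_at_onset) else NA_real_,
      onset_q1 = onset_iqr[1], onset_q3 = onset_iqr[2],
      median_delta = if (nrow(sig)) median(sig$delta_at_onset) else NA_real_,
      delta_q1 = delta_iqr[1], delta_q3 = delta_iqr[2]
    )
  }))
  summary <- tibble::as_tibble(summary[match(methods, summary$method), ])
  structure(
    list(runs = runs, summary = summary, alpha = alpha, seed = seed),
    class = "cohort_method_runs"
  )
}

#' @export
print.cohort_method_runs <- function(x, ...) {
  cat(sprintf("<cohort_method_runs> alpha = %g, %d runs per method\n",
              x$alpha, max(x$runs$run)))
  print(x$summary)
  invisible(x)
}
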