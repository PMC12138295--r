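#' Within-individual sampling of weekend/weekday pairs
#'
#' Repeatedly samples weekend/weekday night pairs from a single
#' participant's data and locates the significance onset of each run with
#' the paired (Wilcoxon signed-rank) test.  Every run's stream is capped at
#' the participant's number of valid weeks, making the three designs
#' comparable:
#'
#' * `pooled`: weekend and weekday values drawn *without replacement* from
#'   the participant's two whole-study pools; pair `k` is the `k`-th weekend
#'   draw with the `k`-th weekday draw.  Controls interindividual
#'   variability only.
#' * `temporal`: valid weeks visited in uniformly random order without
#'   replacement; one uniformly drawn weekend and weekday value from each
#'   visited week.  Also controls which-week variability.
#' * `sequential`: as `temporal` but weeks visited in ascending calendar
#'   order from the participant's first week.
#'
#' Run `r` uses a seed derived deterministically from
#' `(seed, participant, mode, r)`, so any single run is reproducible in
#' isolation.  Per-individual medians of onset and of Cliff's delta at onset
#' are computed over the significant (non-censored) runs only; a participant
#' with no significant run is censored.
#'
#' @param cohort a [night_cohort].
#' @param participant_id participant to sample.
#' @param mode `"pooled"`, `"temporal"` or `"sequential"`.
#' @param n_runs sampling runs for this participant.
#' @param alpha two-sided significance threshold.
#' @param seed master seed.
#' @return a list of class `within_summary`: `participant_id`, `mode`,
#'   `n_valid_weeks`, `n_runs`, `n_significant_runs`, `median_onset`,
#'   `median_delta` (both `NA` when censored), `sign_class` (`"positive"`,
#'   `"negative"`, `"neutral"` or `"censored"`), and `runs`, the per-run
#'   tibble.
#' @export
run_within_individual <- function(cohort, participant_id,
                                  mode = c("pooled", "temporal", "sequential"),
                                  n_runs = 100, alpha = 0.01, seed = 1) {
  mode <- match.arg(mode)
  .assert_prob(alpha, "alpha")
  frame <- .frame_of(cohort)
  i <- match(participant_id, frame$pid)
  if (is.na(i)) {
    stop(sprintf("unknown participant '%s'", participant_id), call. = FALSE)
  }
  res <- .within_engine(frame, i, mode, n_runs, alpha, seed,
                        keep_runs = TRUE)
  res
}

# Core per-participant engine.  `i` is the participant's frame index.
.within_engine <- function(frame, i, mode, n_runs, alpha, seed,
                           keep_runs = FALSE) {
  vw <- .frame_valid_weeks(frame, i)
  nv <- length(vw)
  if (nv == 0L) {
    stop(sprintf("participant '%s' has no valid week", frame$pid[i]),
         call. = FALSE)
  }
  owe <- frame$we$off[i, vw + 1L]; lwe <- frame$we$len[i, vw + 1L]
  owd <- frame$wd$off[i, vw + 1L]; lwd <- frame$wd$len[i, vw + 1L]
  pool_we <- frame$we$vals[frame$we$pool_off[i] + seq_len(frame$we$pool_len[i])]
  pool_wd <- frame$wd$vals[frame$wd$pool_off[i] + seq_len(frame$wd$pool_len[i])]
  vals_we <- frame$we$vals; vals_wd <- frame$wd$vals
  pid_hash <- .hash_string(frame$pid[i])

  onset <- integer(n_runs); pval <- delta <- numeric(n_runs)
  cens <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(.derive_seed(seed, pid_hash, mode, r))
    if (mode == "pooled") {
      we <- pool_we[sample.int(length(pool_we), nv)]
      wd <- pool_wd[sample.int(length(pool_wd), nv)]
    } else {
      ord <- if (mode == "temporal") sample.int(nv) else seq_len(nv)
      we <- vals_we[owe[ord] + floor(runif(nv) * lwe[ord]) + 1L]
      wd <- vals_wd[owd[ord] + floor(runif(nv) * lwd[ord]) + 1L]
    }
    on <- cpp_find_onset(we, wd, TRUE, alpha)
    cens[r] <- on$censored
    onset[r] <- if (on$censored) NA_integer_ else on$n_pairs_at_onset
    pval[r] <- if (on$censored) NA_real_ else on$p_at_onset
    delta[r] <- if (on$censored) NA_real_ else on$delta_at_onset
  }
  n_sig <- sum(!cens)
  med_on <- if (n_sig) median(onset[!cens]) else NA_real_
  med_de <- if (n_sig) median(delta[!cens]) else NA_real_
  sign_class <- if (!n_sig) "censored" else if (med_de > 0) "positive" else
    if (med_de < 0) "negative" else "neutral"
  out <- list(
    participant_id = frame$pid[i], mode = mode,
    n_valid_weeks = nv, n_runs = n_runs, n_significant_runs = n_sig,
    median_onset = med_on, median_delta = med_de, sign_class = sign_class
  )
  if (keep_runs) {
    out$runs <- tibble::tibble(
      run = seq_len(n_runs), n_pairs_at_onset = onset,
      p_at_onset = pval, delta_at_onset = delta, censored = cens
    )
  }
  structure(out, class = "within_summary")
}

#' @export
print.within_summary <- function(x, ...) {
  cat(sprintf(
    "<within_summary> %s (%s): %d/%d runs significant, median onset %s, median delta %s [%s]\n",
    x$participant_id, x$mode, x$n_significant_runs, x$n_runs,
    format(x$median_onset), format(x$median_delta), x$sign_class
  ))
  invisible(x)
}

#' Sweep the within-individual designs over a whole cohort
#'
#' Applies [run_within_individual()] to every participant for each requested
#' mode and stacks the per-individual summaries.
#'
#' @inheritParams run_within_individual
#' @param modes subset of the three designs.
#' @param participants optional subset of participant ids.
#' @return a tibble with one row per participant x mode (columns as in the
#'   `within_summary` fields).
#' @export
run_within_cohort <- function(cohort,
                              modes = c("pooled", "temporal", "sequential"),
                              n_runs = 100, alpha = 0.01, seed = 1,
                              participants = NULL) {
  modes <- match.arg(modes, several.ok = TRUE)
  frame <- .frame_of(cohort)
  idx <- if (is.null(participants)) seq_len(frame$n) else
    match(participants, frame$pid)
  if (anyNA(idx)) stop("unknown participants requested", call. = FALSE)
  rows <- vector("list", length(idx) * length(modes))
  k <- 0L
  for (m in modes) {
    for (i in idx) {
      s <- .within_engine(frame, i, m, n_runs, alpha, seed)
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = s$participant_id, mode = s$mode,
        n_valid_weeks = s$n_valid_weeks, n_runs = s$n_runs,
        n_significant_runs = s$n_significant_runs,
        median_onset = s$median_onset, median_delta = s$median_delta,
        sign_class = s$sign_class, stringsAsFactors = FALSE
      )
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Cohort-level aggregation of within-individual summaries
#'
#' Aggregates per-individual summaries across the three within-individual
#' designs: per-mode medians and IQRs of onset and of Cliff's delta,
#' sign-stratified delta summaries (individuals with negative vs positive
#' median delta), pairwise mode comparisons of onset via the paired
#' signed-rank test (same individuals under every mode), effect-size
#' magnitude comparisons via Kruskal-Wallis with Dunn's post hoc (negative,
#' positive and aggregated components per mode), and Spearman correlations
#' of (runs failed vs weeks available) and (delta magnitude vs weeks
#' available).
#'
#' @param summaries a tibble from [run_within_cohort()] covering the same
#'   participants under every mode.
#' @param restrict_to_all_modes_significant when `TRUE` (default), the
#'   aggregation keeps only individuals who reached significance in at least
#'   one run under *every* mode, so that all per-mode statistics describe
#'   the same set of individuals.
#' @return a list of class `within_aggregate`.
#' @export
aggregate_within <- function(summaries,
                             restrict_to_all_modes_significant = TRUE) {
  stopifnot(is.data.frame(summaries))
  modes <- unique(summaries$mode)
  sets <- lapply(split(summaries$participant_id, summaries$mode),
                 sort)
  if (length(unique(sets)) != 1) {
    stop("summaries must cover the same participants under every mode",
         call. = FALSE)
  }
  n_total <- length(sets[[1]])
  if (restrict_to_all_modes_significant) {
    sig_by_pid <- tapply(summaries$n_significant_runs > 0,
                         summaries$participant_id, all)
    keep <- names(which(sig_by_pid))
    summaries <- summaries[summaries$participant_id %in% keep, , drop = FALSE]
  }
  per_mode <- do.call(rbind, lapply(split(summaries, summaries$mode),
                                    .summarise_mode))
  per_mode <- tibble::as_tibble(per_mode[match(modes, per_mode$mode), ])

  wide_onset <- .pivot_by_mode(summaries, "median_onset", modes)
  wide_delta <- .pivot_by_mode(summaries, "median_delta", modes)
  comp <- list(); ci <- 0L
  if (length(modes) > 1) {
    for (a in seq_along(modes)[-length(modes)]) {
      for (b in (a + 1):length(modes)) {
        d <- wide_onset[, a] - wide_onset[, b]
        t <- wilcoxon_signed_rank(d[!is.na(d)])
        ci <- ci + 1L
        comp[[ci]] <- data.frame(
          mode_a = modes[a], mode_b = modes[b],
          test = "wilcoxon_signed_rank (two-sided, paired)",
          p = t$p_two_sided, n = t$n_effective
        )
      }
    }
  }
  mode_onset_comparisons <- tibble::as_tibble(do.call(rbind, comp))

  delta_magnitude_tests <- lapply(setNames(modes, modes), function(m) {
    d <- summaries$median_delta[summaries$mode == m]
    d <- d[!is.na(d)]
    g <- list(negative = abs(d[d < 0]), positive = abs(d[d > 0]),
              aggregated = abs(d))
    g <- g[lengths(g) > 0]
    if (length(g) < 2) return(NULL)
    kruskal_dunn(g)
  })

  safe_spearman <- function(x, y) {
    tryCatch(spearman_cor(x, y), error = function(e) {
      list(rho = NA_real_, p_two_sided = NA_real_, degenerate = TRUE)
    })
  }
  spearman <- do.call(rbind, lapply(modes, function(m) {
    s <- summaries[summaries$mode == m, , drop = FALSE]
    failed <- safe_spearman(s$n_runs - s$n_significant_runs, s$n_valid_weeks)
    dmag <- safe_spearman(abs(s$median_delta), s$n_valid_weeks)
    data.frame(
      mode = m,
      rho_failed_runs_vs_weeks = failed$rho, p_failed = failed$p_two_sided,
      rho_delta_magnitude_vs_weeks = dmag$rho, p_delta = dmag$p_two_sided
    )
  }))

  structure(
    list(
      n_individuals_total = n_total,
      n_individuals_kept = length(unique(summaries$participant_id)),
      restricted = restrict_to_all_modes_significant,
      per_mode = per_mode,
      mode_onset_comparisons = mode_onset_comparisons,
      delta_magnitude_tests = delta_magnitude_tests,
      spearman_vs_weeks = tibble::as_tibble(spearman),
      summaries = tibble::as_tibble(summaries)
    ),
    class = "within_aggregate"
  )
}

.summarise_mode <- function(s) {
  sig <- s[!is.na(s$median_onset), , drop = FALSE]
  oi <- .iqr_bounds(sig$median_onset)
  di <- .iqr_bounds(sig$median_delta)
  neg <- sig$median_delta[sig$median_delta < 0]
  pos <- sig$median_delta[sig$median_delta > 0]
  ni <- .iqr_bounds(neg); pi <- .iqr_bounds(pos)
  data.frame(
    mode = s$mode[1], n_individuals = nrow(s), n_censored = sum(is.na(s$median_onset)),
    median_onset = if (nrow(sig)) median(sig$median_onset) else NA_real_,
    onset_q1 = oi[1], onset_q3 = oi[2],
    median_delta = if (nrow(sig)) median(sig$median_delta) else NA_real_,
    delta_q1 = di[1], delta_q3 = di[2],
    n_negative = length(neg),
    median_delta_negative = if (length(neg)) median(neg) else NA_real_,
    delta_negative_q1 = ni[1], delta_negative_q3 = ni[2],
    n_positive = length(pos),
    median_delta_positive = if (length(pos)) median(pos) else NA_real_,
    delta_positive_q1 = pi[1], delta_positive_q3 = pi[2],
    n_neutral = sum(sig$median_delta == 0)
  )
}

.pivot_by_mode <- function(summaries, col, modes) {
  pids <- sort(unique(summaries$participant_id))
  out <- sapply(modes, function(m) {
    s <- summaries[summaries$mode == m, , drop = FALSE]
    s[[col]][match(pids, s$participant_id)]
  })
  rownames(out) <- pids
  out
}

#' @export
print.within_aggregate <- function(x, ...) {
  cat(sprintf(
    "<within_aggregate> %d of %d individuals kept%s\n",
    x$n_individuals_kept, x$n_individuals_total,
    if (x$restricted) " (significant under all modes)" else ""
  ))
  print(x$per_mode[, c("mode", "n_individuals", "median_onset",
                       "onset_q1", "onset_q3", "median_delta")])
  invisible(x)
}
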