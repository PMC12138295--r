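#' Configuration for an end-to-end analysis run
#'
#' Collects every tunable of the pipeline with the calibrated defaults.
#' Values can come from a YAML file and/or be overridden by arguments;
#' precedence is arguments > file > defaults.  The master `seed` drives
#' every stage through deterministic derived seeds, and is recorded in the
#' report bundle.
#'
#' @param file optional YAML file with entries named like the arguments
#'   (generator sub-entries under `generator:`).
#' @param generator a [generator_params()] object or a list of overrides for
#'   its arguments.
#' @param cohort_runs replicated datasets for the cohort-wide designs.
#' @param within_runs runs per individual for the within-individual designs.
#' @param alpha_levels significance thresholds to analyse (each in (0, 1)).
#' @param power_test,power_deltas,power_powers,power_reps power-grid options.
#' @param seed master seed.
#' @param out_dir if non-`NULL`, [run_all()] writes the report bundle there.
#' @return a list of class `run_config`.
#' @export
run_config <- function(file = NULL, generator = list(), cohort_runs = 100,
                       within_runs = 100, alpha_levels = c(0.01, 0.05),
                       power_test = "unpaired",
                       power_deltas = c(0.10, 0.30, 0.50),
                       power_powers = 0.80, power_reps = 1000,
                       seed = 1, out_dir = NULL) {
  supplied <- names(match.call())[-1]
  cfg <- list(
    generator = generator, cohort_runs = cohort_runs,
    within_runs = within_runs, alpha_levels = alpha_levels,
    power_test = power_test, power_deltas = power_deltas,
    power_powers = power_powers, power_reps = power_reps,
    seed = seed, out_dir = out_dir
  )
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    for (key in setdiff(names(y), supplied)) cfg[[key]] <- y[[key]]
  }
  if (!inherits(cfg$generator, "generator_params")) {
    cfg$generator <- do.call(generator_params, as.list(cfg$generator))
  }
  for (a in cfg$alpha_levels) .assert_prob(a, "alpha level")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the whole pipeline and collect a machine-readable report
#'
#' Executes, in order: synthetic-cohort generation, the inclusion filters,
#' the descriptive variability analyses (individual vs aggregate SD,
#' seasonal and weekend/weekday contrasts, weekend-effect quartiles), the
#' four cohort-wide sampling designs and the three within-individual designs
#' at every configured alpha, the method comparison table, and the simulated
#' power grid.  Identical configurations (including the seed) produce
#' identical bundles.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return a list of class `report_bundle`; written to `config$out_dir`
#'   (JSON + tidy CSVs) when that is set.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[heteropower] ", fmt), ...))
  }
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed (seed %d): %s",
                   name, config$seed, conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    say("%s done in %.1fs", name, timings[[name]])
    out
  }

  cohort <- stage("generate", generate_cohort(
    config$generator, seed = .derive_seed(config$seed, "generate")
  ))
  filtered <- stage("filter", load_nights(
    data.frame(participant_id = cohort$participant_id,
               date = cohort$night_date, hr = cohort$hr),
    week_start = attr(cohort, "week_start")
  ))
  attr(filtered, "ground_truth") <- ground_truth(cohort)

  variability <- stage("variability", {
    sd_an <- tryCatch(sd_analysis(filtered), error = function(e) NULL)
    seasonal <- window_contrast(.month_values(filtered, 1:2),
                                .month_values(filtered, 3:4))
    weekly <- window_contrast(filtered$hr[filtered$is_weekend],
                              filtered$hr[!filtered$is_weekend])
    quart <- quartile_stratify(filtered)
    list(
      sd = if (is.null(sd_an)) NULL else list(
        n_complete = sd_an$n_complete, aggregate_sd = sd_an$aggregate_sd,
        percentile = sd_an$percentile,
        individual_sd_median = median(sd_an$individual_sds)
      ),
      seasonal = seasonal, weekly = weekly,
      quartiles = quart$quartile_summary,
      quartile_pairwise_p = quart$pairwise_p,
      nightly_medians = nightly_median_series(filtered)
    )
  })

  frame <- .cohort_frame(filtered)
  cohort_methods <- list()
  within <- list()
  for (a in config$alpha_levels) {
    key <- format(a)
    cohort_methods[[key]] <- stage(
      paste0("cohort_sampling@", key),
      run_cohort_methods(frame, n_runs = config$cohort_runs, alpha = a,
                         seed = .derive_seed(config$seed, "cohort", key))
    )
    sweeps <- stage(
      paste0("within_sampling@", key),
      run_within_cohort(frame, n_runs = config$within_runs, alpha = a,
                        seed = .derive_seed(config$seed, "within", key))
    )
    within[[key]] <- aggregate_within(sweeps)
  }

  comparison <- stage("compare", compare_methods(
    cohort_runs = cohort_methods[[1]]$runs,
    within_summaries = within[[1]]$summaries
  ))

  power <- stage("power", power_grid(
    test = config$power_test, deltas = config$power_deltas,
    powers = config$power_powers, reps = config$power_reps,
    seed = .derive_seed(config$seed, "powergrid")
  ))

  bundle <- structure(
    list(
      seed = config$seed,
      config = unclass(config)[setdiff(names(config), "out_dir")],
      filter_report = filter_report(filtered),
      variability = variability,
      cohort_methods = cohort_methods,
      within = within,
      comparison = comparison,
      power_grid = power,
      timings = timings,
      total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "report_bundle"
  )
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (the summary sections; master seed included) plus
#' tidy CSVs: per-run cohort-design results, per-individual within-design
#' summaries, the quartile table, the nightly-median series and the power
#' grid.
#'
#' @param bundle a `report_bundle` from [run_all()].
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  }
  for (key in names(bundle$cohort_methods)) {
    w(bundle$cohort_methods[[key]]$runs,
      sprintf("cohort_runs_alpha_%s.csv", key))
  }
  for (key in names(bundle$within)) {
    w(bundle$within[[key]]$summaries,
      sprintf("within_individuals_alpha_%s.csv", key))
  }
  w(bundle$variability$quartiles, "quartiles.csv")
  w(bundle$variability$nightly_medians, "nightly_medians.csv")
  w(bundle$power_grid, "power_grid.csv")

  slim <- list(
    seed = bundle$seed,
    generator = bundle$config$generator[
      setdiff(names(bundle$config$generator), "week_start")],
    week_start = as.character(bundle$config$generator$week_start),
    filter_report = bundle$filter_report[
      setdiff(names(bundle$filter_report),
              c("removed_by_hr_bounds", "removed_by_week_validity"))],
    variability = list(
      sd = bundle$variability$sd,
      seasonal = bundle$variability$seasonal,
      weekly = bundle$variability$weekly,
      quartiles = bundle$variability$quartiles
    ),
    cohort_methods = lapply(bundle$cohort_methods, function(x) x$summary),
    within = lapply(bundle$within, function(x) list(
      n_individuals_total = x$n_individuals_total,
      n_individuals_kept = x$n_individuals_kept,
      per_mode = x$per_mode,
      spearman_vs_weeks = x$spearman_vs_weeks
    )),
    power_grid = bundle$power_grid
  )
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> seed %d, %.1fs total\n",
              x$seed, x$total_seconds))
  for (key in names(x$cohort_methods)) {
    cat(sprintf("-- cohort-wide designs, alpha = %s\n", key))
    print(x$cohort_methods[[key]]$summary[, c("method", "median_onset",
                                              "median_delta", "n_censored")])
  }
  for (key in names(x$within)) {
    cat(sprintf("-- within-individual designs, alpha = %s\n", key))
    print(x$within[[key]]$per_mode[, c("mode", "median_onset",
                                       "median_delta", "n_individuals")])
  }
  invisible(x)
}

#' Compare sampling designs on onset counts and effect sizes
#'
#' Builds the method-comparison table: per-design medians/IQRs and
#' means/SDs of onset and Cliff's delta, pairwise onset comparisons (the
#' unpaired Mann-Whitney U between cohort-wide designs, whose runs are
#' independent; the paired Wilcoxon signed-rank between within-individual
#' designs, evaluated on the same individuals; unpaired across the two
#' families), and a Kruskal-Wallis + Dunn panel over the delta
#' distributions of all designs.  Every pairwise cell names its test; all
#' tests are two-sided.
#'
#' @param cohort_runs per-run tibble from [run_cohort_methods()] (`$runs`),
#'   or `NULL`.
#' @param within_summaries per-individual tibble from [run_within_cohort()]
#'   or the `$summaries` of [aggregate_within()], or `NULL`.
#' @return a list of class `comparison_table`.
#' @export
compare_methods <- function(cohort_runs = NULL, within_summaries = NULL) {
  pools <- list()   # onset / delta distributions per design
  family <- character()
  if (!is.null(cohort_runs)) {
    for (m in unique(cohort_runs$method)) {
      d <- cohort_runs[cohort_runs$method == m & !cohort_runs$censored, ,
                       drop = FALSE]
      pools[[m]] <- list(onset = d$n_pairs_at_onset, delta = d$delta_at_onset)
      family[m] <- "cohort"
    }
  }
  if (!is.null(within_summaries)) {
    for (m in unique(within_summaries$mode)) {
      d <- within_summaries[within_summaries$mode == m &
                              !is.na(within_summaries$median_onset), ,
                            drop = FALSE]
      pools[[paste0("within_", m)]] <-
        list(onset = d$median_onset, delta = d$median_delta,
             pid = d$participant_id)
      family[paste0("within_", m)] <- "within"
    }
  }
  if (length(pools) < 2) {
    stop("need at least two designs to compare", call. = FALSE)
  }

  summary <- do.call(rbind, lapply(names(pools), function(m) {
    o <- pools[[m]]$onset; de <- pools[[m]]$delta
    oi <- .iqr_bounds(o); di <- .iqr_bounds(de)
    med <- function(v) if (length(v)) median(v) else NA_real_
    data.frame(
      method = m, family = family[m], n = length(o),
      median_onset = med(o), onset_q1 = oi[1], onset_q3 = oi[2],
      mean_onset = if (length(o)) mean(o) else NA_real_, sd_onset = sd(o),
      median_delta = med(de), delta_q1 = di[1], delta_q3 = di[2],
      mean_delta = if (length(de)) mean(de) else NA_real_, sd_delta = sd(de)
    )
  }))

  nm <- names(pools)
  pw <- list(); k <- 0L
  for (a in seq_along(nm)[-length(nm)]) {
    for (b in (a + 1):length(nm)) {
      paired <- family[nm[a]] == "within" && family[nm[b]] == "within"
      if (paired) {
        common <- intersect(pools[[nm[a]]]$pid, pools[[nm[b]]]$pid)
        da <- pools[[nm[a]]]$onset[match(common, pools[[nm[a]]]$pid)]
        db <- pools[[nm[b]]]$onset[match(common, pools[[nm[b]]]$pid)]
        t <- if (length(common)) wilcoxon_signed_rank(da - db) else
          list(p_two_sided = NA_real_)
        lab <- "wilcoxon_signed_rank (two-sided, paired)"
      } else {
        oa <- pools[[nm[a]]]$onset; ob <- pools[[nm[b]]]$onset
        t <- if (length(oa) && length(ob)) mann_whitney_u(oa, ob) else
          list(p_two_sided = NA_real_) # a design with every run censored
        lab <- "mann_whitney_u (two-sided, unpaired)"
      }
      k <- k + 1L
      pw[[k]] <- data.frame(method_a = nm[a], method_b = nm[b],
                            test = lab, p = t$p_two_sided)
    }
  }

  deltas <- lapply(pools, `[[`, "delta")
  deltas <- deltas[lengths(deltas) > 0]
  effect_panel <- if (length(deltas) >= 2) kruskal_dunn(deltas) else NULL

  structure(
    list(
      summary = tibble::as_tibble(summary),
      pairwise_onset = tibble::as_tibble(do.call(rbind, pw)),
      effect_size_panel = effect_panel
    ),
    class = "comparison_table"
  )
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table>\n")
  print(x$summary[, c("method", "n", "median_onset", "median_delta")])
  print(x$pairwise_onset)
  invisible(x)
}
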