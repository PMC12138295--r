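#' Convert Cliff's delta to a standardized normal shift
#'
#' For two equal-variance normal samples separated by a mean shift of
#' `mu/sigma` standard deviations, `P(X > Y) = Phi(shift / sqrt(2))`.
#' Inverting at `P(X > Y) = (delta + 1) / 2` gives
#' `shift = sqrt(2) * qnorm((delta + 1) / 2)`, the shift at which the two
#' normals realize a target Cliff's delta.
#'
#' @param delta Cliff's delta target, strictly between -1 and 1.
#' @return the standardized mean difference.
#' @examples
#' delta_to_shift(0.5) # ~0.954
#' @export
delta_to_shift <- function(delta) {
  if (!is.numeric(delta) || any(abs(delta) >= 1)) {
    stop("delta must lie strictly between -1 and 1", call. = FALSE)
  }
  sqrt(2) * qnorm((delta + 1) / 2)
}

# Monte-Carlo power of the two-sided test at n pairs; reps replicates.
.mc_power <- function(test, n, shift, alpha, reps) {
  hits <- 0L
  if (test == "unpaired") {
    for (r in seq_len(reps)) {
      p <- cpp_rank_sum_p(rnorm(n) + shift, rnorm(n))
      hits <- hits + (p < alpha)
    }
  } else {
    sdd <- sqrt(2) # difference of two unit-variance normals
    for (r in seq_len(reps)) {
      p <- cpp_signed_rank_p(rnorm(n, shift, sdd))
      hits <- hits + (p < alpha)
    }
  }
  hits / reps
}

#' Pairs of samples required to reach a target power
#'
#' Monte-Carlo sample-size search for the two-sided Mann-Whitney U
#' (`test = "unpaired"`) or Wilcoxon signed-rank (`test = "paired"`) test on
#' simulated normal data at a given Cliff's delta.  One *pair* is one
#' weekend-like and one weekday-like draw: the unpaired test compares the
#' two pools of `n` draws; the paired test uses the `n` within-pair
#' differences.  Draws are independent within a pair (no induced
#' correlation) unless `correlation` is set.
#'
#' Power at a candidate `n` is the fraction of `reps` simulated datasets
#' whose p-value falls below `alpha`; `n_required` is located by doubling
#' until the target power is bracketed, then bisecting to unit resolution.
#' A target power of 1 is unattainable in finite samples and is mapped to
#' 0.995 with a warning.
#'
#' @param test `"unpaired"` or `"paired"`.
#' @param delta target Cliff's delta in (0, 1).
#' @param power target power in (0, 1]; 1 is mapped to 0.995.
#' @param alpha two-sided significance threshold.
#' @param reps Monte-Carlo replicates per candidate sample size (>= 200).
#' @param seed RNG seed.
#' @param correlation within-pair correlation of the simulated normals.
#' @param n_max search ceiling; if the target power is not reached by
#'   `n_max` the result is flagged `unreachable` (never silently returned).
#' @return a list of class `power_cell`: `test`, `delta`, `power` (target),
#'   `alpha`, `n_required`, `power_at_n` (estimate at `n_required`), `reps`,
#'   `seed`, `unreachable`.
#' @export
required_pairs <- function(test = c("unpaired", "paired"), delta, power,
                           alpha = 0.01, reps = 1000, seed = NULL,
                           correlation = 0, n_max = 65536L) {
  test <- match.arg(test)
  stopifnot(delta > 0, delta < 1, reps >= 200)
  .assert_prob(alpha, "alpha")
  if (power >= 1) {
    warning("target power 1 is unattainable; using 0.995")
    power <- 0.995
  }
  .assert_prob(power, "power")
  if (!is.null(seed)) set.seed(seed)
  shift <- delta_to_shift(delta)
  pw <- function(n) {
    if (test == "paired" && correlation != 0) {
      # correlated pairs shrink the SD of the within-pair difference
      sdd <- sqrt(2 * (1 - correlation))
      mean(replicate(reps, cpp_signed_rank_p(rnorm(n, shift, sdd))) < alpha)
    } else {
      .mc_power(test, n, shift, alpha, reps)
    }
  }
  lo <- 1L; hi <- 2L
  p_hi <- pw(hi)
  while (p_hi < power && hi < n_max) {
    lo <- hi; hi <- min(2L * hi, n_max)
    p_hi <- pw(hi)
  }
  if (p_hi < power) {
    return(structure(
      list(test = test, delta = delta, power = power, alpha = alpha,
           n_required = NA_integer_, power_at_n = p_hi, reps = reps,
           seed = seed, unreachable = TRUE),
      class = "power_cell"
    ))
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    p_mid <- pw(mid)
    if (p_mid >= power) { hi <- mid; p_hi <- p_mid } else lo <- mid
  }
  structure(
    list(test = test, delta = delta, power = power, alpha = alpha,
         n_required = hi, power_at_n = p_hi, reps = reps, seed = seed,
         unreachable = FALSE),
    class = "power_cell"
  )
}

#' @export
print.power_cell <- function(x, ...) {
  cat(sprintf(
    "<power_cell> %s test, delta = %.2f, power = %.2f, alpha = %g: n = %s\n",
    x$test, x$delta, x$power, x$alpha,
    if (x$unreachable) "unreachable" else x$n_required
  ))
  invisible(x)
}

#' Grid of required pairs over Cliff's delta and target power
#'
#' Evaluates [required_pairs()] over the cross product of `deltas` and
#' `powers`; each cell uses a seed derived from `seed` so the grid is
#' reproducible cell by cell.
#'
#' @inheritParams required_pairs
#' @param deltas,powers non-empty grids.
#' @param seed master seed.
#' @return a tibble with one row per cell: `test`, `delta`, `power`,
#'   `alpha`, `n_required`, `power_at_n`, `unreachable`.
#' @export
power_grid <- function(test = c("unpaired", "paired"),
                       deltas = seq(0.05, 0.95, by = 0.05),
                       powers = seq(0.05, 1.00, by = 0.05),
                       alpha = 0.01, reps = 1000, seed = 1) {
  test <- match.arg(test)
  stopifnot(length(deltas) > 0, length(powers) > 0)
  rows <- list(); k <- 0L
  for (d in deltas) {
    for (p in powers) {
      cell <- suppressWarnings(required_pairs(
        test, d, p, alpha = alpha, reps = reps,
        seed = .derive_seed(seed, "power", round(d * 1000), round(p * 1000))
      ))
      k <- k + 1L
      rows[[k]] <- data.frame(
        test = test, delta = d, power = p, alpha = alpha,
        n_required = cell$n_required, power_at_n = cell$power_at_n,
        unreachable = cell$unreachable
      )
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
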