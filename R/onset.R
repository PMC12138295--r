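#' Significance onset of a stream of weekend/weekday pairs
#'
#' The central sequential statistic: iterate over an ordered stream of
#' weekend/weekday heart-rate pairs, at each iteration `k` test the first
#' `k` pairs with a two-sided test, and return the smallest `k` at which
#' `p < alpha`, together with Cliff's delta computed on the values up to and
#' including that iteration (weekend values as the first sample, so positive
#' delta means weekend heart rate higher).
#'
#' * `test = "unpaired"` pools the weekend values against the weekday values
#'   and applies the Mann-Whitney U test;
#' * `test = "paired"` applies the Wilcoxon signed-rank test to the per-pair
#'   differences.
#'
#' Testing starts at `k = 1`; degenerate prefixes (all differences zero, all
#' values tied) simply count as non-significant.  If no prefix reaches
#' `p < alpha` the result is censored.  No multiplicity correction is applied
#' across iterations -- the procedure deliberately mimics naive sequential
#' testing, whose behaviour is the object of study.
#'
#' @param pairs a data frame with numeric columns `weekend_hr` and
#'   `weekday_hr` (a stream of pair observations in sampling order).
#' @param test `"unpaired"` or `"paired"`.
#' @param alpha two-sided significance threshold in (0, 1).
#' @return a list of class `onset_result`: `n_pairs_at_onset` (`NULL` when
#'   censored), `p_at_onset`, `delta_at_onset`, `censored`, `n_available`.
#' @examples
#' stream <- data.frame(weekend_hr = 62 + 1:10 / 100,
#'                      weekday_hr = 60 + 1:10 / 100)
#' find_onset(stream, test = "paired", alpha = 0.01)
#' @export
find_onset <- function(pairs, test = c("unpaired", "paired"), alpha = 0.01) {
  test <- match.arg(test)
  .assert_prob(alpha, "alpha")
  if (!all(c("weekend_hr", "weekday_hr") %in% names(pairs))) {
    stop("pairs must have columns weekend_hr and weekday_hr", call. = FALSE)
  }
  we <- as.numeric(pairs$weekend_hr)
  wd <- as.numeric(pairs$weekday_hr)
  if (length(we) == 0) stop("empty stream", call. = FALSE)
  if (anyNA(we) || anyNA(wd)) stop("NA heart-rate values", call. = FALSE)
  raw <- cpp_find_onset(we, wd, test == "paired", alpha)
  structure(
    list(
      n_pairs_at_onset = if (raw$censored) NULL else raw$n_pairs_at_onset,
      p_at_onset = if (raw$censored) NULL else raw$p_at_onset,
      delta_at_onset = if (raw$censored) NULL else raw$delta_at_onset,
      censored = raw$censored,
      n_available = raw$n_available,
      test = test, alpha = alpha
    ),
    class = "onset_result"
  )
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<onset_result> censored after %d pairs (%s, alpha = %g)\n",
                x$n_available, x$test, x$alpha))
  } else {
    cat(sprintf(
      "<onset_result> onset at %d of %d pairs, p = %.4g, delta = %.3f (%s)\n",
      x$n_pairs_at_onset, x$n_available, x$p_at_onset, x$delta_at_onset,
      x$test
    ))
  }
  invisible(x)
}
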