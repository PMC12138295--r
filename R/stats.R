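#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| * |y|)`, the difference
#' between the probabilities that a value drawn from `x` exceeds, versus
#' falls below, a value drawn from `y`.  `+1` means complete separation with
#' `x` above `y`, `0` stochastic equality; positive values mean `x`
#' stochastically larger.
#'
#' @param x,y non-empty numeric samples.
#' @return a number in `[-1, 1]`.
#' @examples
#' cliffs_delta(c(3, 4, 5), c(1, 2, 3)) # 8/9
#' @export
cliffs_delta <- function(x, y) {
  .check_sample(x, "x"); .check_sample(y, "y")
  cpp_cliffs_delta(as.numeric(x), as.numeric(y))
}

.check_sample <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("%s must be a non-empty numeric sample without NA/Inf",
                 name), call. = FALSE)
  }
}

.as_hp_test <- function(raw, test) {
  structure(
    list(statistic = raw$statistic, p_two_sided = raw$p_two_sided,
         n_effective = raw$n_effective, method = raw$method, test = test),
    class = "hp_test"
  )
}

#' @export
print.hp_test <- function(x, ...) {
  cat(sprintf("<hp_test: %s (%s)> statistic = %g, p = %.6g, n = %d\n",
              x$test, x$method, x$statistic, x$p_two_sided, x$n_effective))
  invisible(x)
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped before ranking (Wilcoxon's original
#' treatment).  The p-value comes from the exact signed-rank null when the
#' number of non-zero differences is at most 25 and their magnitudes are
#' untied; otherwise a tie-corrected normal approximation with continuity
#' correction is used (matching `stats::wilcox.test(correct = TRUE)`).  If
#' every difference is zero the result is degenerate with `p = 1`.
#'
#' The exact null is discrete: the smallest attainable two-sided p with `n`
#' non-zero differences is `2 * 2^-n`, so significance at alpha = .01
#' requires at least 8 informative pairs.
#'
#' @param diffs numeric vector of paired differences.
#' @return an `hp_test` list: `statistic` (W, the positive-rank sum),
#'   `p_two_sided`, `n_effective` (non-zero differences), `method`
#'   (`"exact"`, `"approximate"` or `"degenerate"`).
#' @export
wilcoxon_signed_rank <- function(diffs) {
  if (!is.numeric(diffs) || length(diffs) == 0 || anyNA(diffs)) {
    stop("diffs must be a non-empty numeric vector without NA", call. = FALSE)
  }
  .as_hp_test(cpp_signed_rank(as.numeric(diffs)), "wilcoxon_signed_rank")
}

#' Two-sided Mann-Whitney U test
#'
#' `statistic` is U counted as x-over-y wins (midranks for ties).  The exact
#' rank-sum null is used when the smaller group has at most 8 observations
#' and no value is shared across groups; otherwise a tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @return an `hp_test` list (see [wilcoxon_signed_rank()]).
#' @export
mann_whitney_u <- function(x, y) {
  .check_sample(x, "x"); .check_sample(y, "y")
  .as_hp_test(cpp_rank_sum(as.numeric(x), as.numeric(y)), "mann_whitney_u")
}

#' Spearman rank correlation with two-sided p-value
#'
#' Thin wrapper over `stats::cor.test(method = "spearman")` using the
#' asymptotic t approximation (ties are common in onset counts).  Constant
#' input makes the correlation undefined; the result is then flagged
#' degenerate with `rho = NA`.
#'
#' @param x,y paired numeric vectors, at least 3 points.
#' @return a list with `rho`, `p_two_sided`, `n`, `degenerate`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p_two_sided = NA_real_, n = length(x),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_two_sided = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' The omnibus test is `stats::kruskal.test`.  Dunn's z statistics use
#' pooled midranks with the tie correction
#' `sigma_ij^2 = (N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j)`,
#' two-sided p-values, Holm-adjusted across all pairs.
#'
#' @param groups named list of numeric vectors (at least 2 groups).
#' @return a list with `omnibus_p`, `z` matrix, `p_unadjusted` and
#'   `p_adjusted` matrices (Holm), and per-group mean ranks.
#' @export
kruskal_dunn <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("groups must be a list of at least 2 numeric vectors", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  for (g in groups) .check_sample(g, "each group")
  k <- length(groups)
  omni <- kruskal.test(groups)$p.value
  x <- unlist(groups, use.names = FALSE)
  gidx <- rep(seq_len(k), lengths(groups))
  r <- rank(x)
  N <- length(x)
  rbar <- tapply(r, gidx, mean)
  n_i <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  z <- p_raw <- matrix(NA_real_, k, k,
                       dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s2 <- (N * (N + 1) / 12 - tie_term) * (1 / n_i[i] + 1 / n_i[j])
      zij <- (rbar[i] - rbar[j]) / sqrt(s2)
      z[i, j] <- z[j, i] <- zij
      p_raw[i, j] <- p_raw[j, i] <- 2 * pnorm(-abs(zij))
    }
  }
  upper <- upper.tri(p_raw)
  p_adj <- p_raw
  p_adj[upper] <- p.adjust(p_raw[upper], method = "holm")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(omnibus_p = omni, z = z, p_unadjusted = p_raw, p_adjusted = p_adj,
       mean_ranks = setNames(as.numeric(rbar), names(groups)))
}
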