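# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own kernels: delta by full pair counting, exact rank
# tests by complete enumeration of the permutation null.

oracle_cliffs_delta <- function(x, y) {
  mean(outer(x, y, ">")) - mean(outer(x, y, "<"))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the observed |d| (zeros dropped); two-sided as twice the smaller tail
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  a <- abs(d)
  r <- rank(a)
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Wnull <= W), mean(Wnull >= W)))
}

# exact two-sided Mann-Whitney p by enumerating all C(m+n, m) group labelings
# of the pooled sample (midrank U for ties)
oracle_mann_whitney_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  U_of <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  U <- U_of(seq_len(m))
  Unull <- apply(utils::combn(m + n, m), 2, U_of)
  min(1, 2 * min(mean(Unull <= U), mean(Unull >= U)))
}

# brute-force onset: re-test every prefix with the package's public tests
oracle_onset <- function(we, wd, test, alpha) {
  for (k in seq_along(we)) {
    p <- if (test == "paired") {
      wilcoxon_signed_rank(we[1:k] - wd[1:k])$p_two_sided
    } else {
      mann_whitney_u(we[1:k], wd[1:k])$p_two_sided
    }
    if (p < alpha) return(k)
  }
  NA_integer_
}

# small long-format data frame -> night_cohort via the public loader
as_cohort <- function(df, ...) {
  load_nights(data.frame(participant_id = df$participant_id,
                         date = df$night_date, hr = df$hr), ...)
}
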