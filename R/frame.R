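# Internal indexed view of a cohort used by the resampling engines.
#
# Heart-rate values are stored in two flat vectors (weekend / weekday),
# sorted by (participant, week), with per-(participant, week) offsets and
# lengths, per-participant whole-study pools, and the list of valid weeks
# (weeks holding at least one value of each kind).  All downstream sampling
# is O(1) vectorized gathers into these arrays.

.cohort_frame <- function(cohort) {
  stopifnot(inherits(cohort, "night_cohort"))
  pid_levels <- sort(unique(cohort$participant_id))
  n <- length(pid_levels)
  W <- max(cohort$week_id) + 1L
  i <- match(cohort$participant_id, pid_levels)
  wk <- cohort$week_id
  key <- (i - 1L) * W + wk + 1L

  pack <- function(sel) {
    ord <- order(key[sel])
    vals <- cohort$hr[sel][ord]
    tab <- tabulate(key[sel], nbins = n * W)
    len <- matrix(tab, n, W, byrow = TRUE)
    off <- matrix(head(cumsum(c(0L, tab)), n * W), n, W, byrow = TRUE)
    list(vals = vals, len = len, off = off,
         pool_len = rowSums(len),
         pool_off = c(0L, head(cumsum(rowSums(len)), n - 1L)))
  }
  we <- pack(cohort$is_weekend)
  wd <- pack(!cohort$is_weekend)

  vmat <- we$len > 0L & wd$len > 0L
  idx <- which(t(vmat))
  vw_flat <- (idx - 1L) %% W                     # 0-based valid weeks,
  vw_part <- (idx - 1L) %/% W + 1L               # ascending within participant
  vw_len <- as.integer(rowSums(vmat))
  vw_off <- c(0L, head(cumsum(vw_len), n - 1L))
  stopifnot(identical(vw_part, rep(seq_len(n), times = vw_len)))

  list(
    pid = pid_levels, n = n, n_weeks = W,
    we = we, wd = wd,
    vw_flat = vw_flat, vw_off = vw_off, vw_len = vw_len
  )
}

.frame_of <- function(x) {
  if (inherits(x, "night_cohort")) .cohort_frame(x)
  else if (is.list(x) && !is.null(x$vw_flat)) x
  else stop("expected a night_cohort", call. = FALSE)
}

# valid weeks (0-based) of participant index i
.frame_valid_weeks <- function(frame, i) {
  if (frame$vw_len[i] == 0L) return(integer())
  frame$vw_flat[frame$vw_off[i] + seq_len(frame$vw_len[i])]
}
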