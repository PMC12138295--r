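# Internal helpers: day-of-week handling, deterministic seed derivation,
# quantile conventions.

# 0 = Sunday ... 6 = Saturday, locale independent
.wday <- function(dates) as.POSIXlt(dates)$wday

.DAY_NAMES <- c(
  sunday = 0L, monday = 1L, tuesday = 2L, wednesday = 3L,
  thursday = 4L, friday = 5L, saturday = 6L
)

.day_numbers <- function(days) {
  if (is.numeric(days)) {
    d <- as.integer(days)
  } else {
    d <- .DAY_NAMES[tolower(as.character(days))]
  }
  if (anyNA(d) || any(d < 0L | d > 6L)) {
    stop("weekend_days must be day names (e.g. 'Friday') or integers 0-6",
         call. = FALSE)
  }
  unname(d)
}

# Monday on or before `date`
.monday_on_or_before <- function(date) {
  date - ((.wday(date) - 1L) %% 7L)
}

.SEED_MOD <- 2147483587 # prime below 2^31; products stay exact in doubles

.hash_string <- function(s) {
  h <- 5381
  for (c in utf8ToInt(s)) h <- (h * 33 + c) %% .SEED_MOD
  h
}

# Deterministic 31-bit seed from a master seed plus arbitrary labels, so any
# single resampling run is reproducible in isolation.
.derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% .SEED_MOD
  for (part in list(...)) {
    v <- if (is.character(part)) .hash_string(part) else as.numeric(part)
    h <- (h * 48271 + v) %% .SEED_MOD
  }
  as.integer(h)
}

# interquartile range endpoints (type 7, the default quantile definition)
.iqr_bounds <- function(x) {
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  unname(quantile(x, c(0.25, 0.75), names = FALSE))
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("%s must be a single number in (0, 1)", name), call. = FALSE)
  }
}

# uniform draw of one index per element from pools of heterogeneous sizes
.runif_index <- function(sizes) {
  ifelse(sizes > 0L, floor(runif(length(sizes)) * sizes) + 1L, NA_integer_)
}
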