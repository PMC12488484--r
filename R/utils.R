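#' Convert seconds to a frame count
#'
#' Times in this package are seconds from session start; frame indices are
#' 1-based and windows are half-open `[start, end)`. At 15 Hz the canonical
#' window durations (0.33 s, 0.67 s, 0.93 s, ...) are integer frame
#' multiples of 1/15 s, so `round()` is exact there.
#'
#' @param t time in seconds (scalar or vector)
#' @param fs_hz sampling rate in Hz
#' @return integer number of frames
#' @export
sec_to_frames <- function(t, fs_hz) {
  as.integer(round(t * fs_hz))
}

# Deterministic per-purpose seed derived from one master seed, so each
# generator (behaviour, activity, structure, shuffles) has its own
# substream and can be regenerated independently. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  s <- abs(as.numeric(seed)) %% 2147483647
  as.integer((s * 1009 + h * 97) %% 2147483647)
}

# stop() with the offending field named, used by configuration validators
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

# Pearson correlation that returns NA (with no warning) on zero variance,
# so degenerate trajectories/vectors are flagged rather than propagated.
safe_cor <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# half-open membership t in [lo, hi)
in_window <- function(t, lo, hi) t >= lo & t < hi
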