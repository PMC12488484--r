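#' Compute dF/F with a sliding-percentile baseline
#'
#' The baseline F0 at each frame is a percentile (default the 30th) of the
#' raw fluorescence inside a sliding window (default 30 s), centred on the
#' frame and truncated at the segment edges (`align = "trailing"` uses the
#' preceding window instead). dF/F is `(F - F0) / F0`; the z-scored trace
#' standardises dF/F to mean 0, s.d. 1 over the segment, so downstream
#' thresholds are in z units.
#'
#' @param raw_f positive raw fluorescence trace (one ROI)
#' @param fs_hz sampling rate (Hz)
#' @param window_s baseline window length (s, default 30)
#' @param percentile baseline percentile (default 30)
#' @param zscore compute the z-scored trace (default TRUE)
#' @param align `"centered"` (default) or `"trailing"` baseline window
#' @return list of class `dff_trace`: `dff`, `f0`, `z` (or `NULL`),
#'   `fs_hz`
#' @export
compute_dff <- function(raw_f, fs_hz, window_s = 30, percentile = 30,
                        zscore = TRUE, align = c("centered", "trailing")) {
  align <- match.arg(align)
  if (!all(is.finite(raw_f))) stop("raw fluorescence must be finite")
  if (length(raw_f) < window_s * fs_hz)
    stop(sprintf("trace too short for baseline estimation (need >= %g s)",
                 window_s))
  w <- sec_to_frames(window_s, fs_hz)
  hw <- w %/% 2L
  off <- if (align == "centered") c(-hw, hw) else c(-(w - 1L), 0L)
  f0 <- .sliding_percentile_cpp(as.numeric(raw_f), off[1], off[2],
                                percentile / 100)
  bad <- which(f0 <= 0)
  if (length(bad))
    stop(sprintf("baseline F0 <= 0 at %d frame(s) (first: %d)",
                 length(bad), bad[1]))
  dff <- (raw_f - f0) / f0
  z <- NULL
  if (zscore) {
    s <- stats::sd(dff)
    z <- if (s > 0) (dff - mean(dff)) / s else dff * 0
  }
  out <- list(dff = dff, f0 = f0, z = z, fs_hz = fs_hz)
  class(out) <- "dff_trace"
  out
}

#' Detect calcium events on a z-scored trace
#'
#' An event is a strict local maximum of the z-scored dF/F whose height
#' exceeds `threshold_sd` (in z units, i.e. multiples of the segment
#' s.d.). Plateaus of equal values count once, at their first frame;
#' segment endpoints are never peaks. Returns an empty series when nothing
#' crosses threshold.
#'
#' @param trace a `dff_trace` (its `z` is used) or a numeric z-scored trace
#' @param threshold_sd detection threshold in z units (default 1)
#' @param fs_hz sampling rate; taken from the `dff_trace` when omitted
#' @return data frame of class `event_series`: `frame` (1-based),
#'   `time_s`, `amplitude_z`, sorted by time
#' @export
detect_events <- function(trace, threshold_sd = 1, fs_hz = NULL) {
  if (inherits(trace, "dff_trace")) {
    z <- trace$z
    if (is.null(z)) stop("dff_trace has no z-scored component")
    if (is.null(fs_hz)) fs_hz <- trace$fs_hz
  } else z <- as.numeric(trace)
  if (is.null(fs_hz)) stop("fs_hz required for a bare numeric trace")

  n <- length(z)
  frames <- integer(0)
  if (n >= 3) {
    if (!any(diff(z) == 0)) {
      # no plateaus: strict local maxima, vectorised
      mid <- 2:(n - 1)
      frames <- mid[z[mid] > z[mid - 1] & z[mid] > z[mid + 1] &
                      z[mid] > threshold_sd]
    } else {
      # collapse plateaus to their first frame, then test run neighbours
      r <- rle(z)
      k <- length(r$values)
      if (k >= 3) {
        starts <- cumsum(r$lengths) - r$lengths + 1L
        mid <- 2:(k - 1)
        is_peak <- r$values[mid] > r$values[mid - 1] &
          r$values[mid] > r$values[mid + 1] &
          r$values[mid] > threshold_sd
        frames <- starts[mid][is_peak]
      }
    }
  }
  ev <- data.frame(frame = frames, time_s = (frames - 1) / fs_hz,
                   amplitude_z = z[frames])
  class(ev) <- c("event_series", "data.frame")
  ev
}
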