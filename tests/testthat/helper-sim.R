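# Small configurations and constructed traces shared across test files.

tiny_cfg <- function(...) {
  args <- list(...)
  base <- list(n_axons = 3, boutons_per_axon = 3, segment_s = 300,
               n_trials = 12, iti_push_rate_hz = 0.02, seed = 1)
  base[names(args)] <- args
  do.call(sim_config, base)
}

# unlocked-activity config: all events Poisson in time, no movement lock
unlocked_cfg <- function(shared = 0.7, n_axons = 3, boutons = 3,
                         segment_s = 1200, events = 60, seed = 1, ...) {
  tiny_cfg(n_axons = n_axons, boutons_per_axon = boutons,
           segment_s = segment_s, n_trials = 3, iti_push_rate_hz = 0,
           shared_event_fraction = shared,
           event_rate_hz = events / segment_s,
           category_mix = c(RM_only = 0, UM_only = 0, both = 0,
                            unresponsive = 1),
           seed = seed, ...)
}

# lever trace with raised-cosine pulses at given onsets (no rest noise)
pulse_lever <- function(onsets, amps, dur = 0.4, fs = 20, total_s = 30) {
  tt <- seq(0, total_s, by = 1 / fs)
  pos <- numeric(length(tt))
  for (k in seq_along(onsets)) {
    sel <- tt >= onsets[k] & tt <= onsets[k] + dur
    pos[sel] <- pos[sel] + amps[k] * sin(pi * (tt[sel] - onsets[k]) / dur)^2
  }
  data.frame(time_s = tt, position_mm = pos)
}

# z trace with Gaussian bumps of given apex heights at given frames
bump_trace <- function(n, frames, heights, width = 5) {
  z <- numeric(n)
  for (k in seq_along(frames))
    z <- z + heights[k] * exp(-0.5 * ((seq_len(n) - frames[k]) / width)^2)
  z
}

# event data frame from times
ev_df <- function(times) {
  data.frame(frame = round(times * 15) + 1L, time_s = times,
             amplitude_z = rep(2, length(times)))
}

# brute-force sliding percentile (independent oracle for compute_dff)
bf_percentile <- function(x, w, prob, align = "centered") {
  n <- length(x)
  hw <- w %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- if (align == "centered") max(1, i - hw):min(n, i + hw)
    else max(1, i - w + 1L):i
    as.numeric(quantile(x[idx], prob, type = 7))
  }, numeric(1))
}

# brute-force event detection (independent oracle for detect_events)
bf_detect <- function(z, thr) {
  which(vapply(seq_along(z), function(i) {
    i > 1 && i < length(z) && z[i] > z[i - 1] && z[i] > z[i + 1] &&
      z[i] > thr
  }, logical(1)))
}

# F1 of detected event times against true event times
event_f1 <- function(det_times, true_times, tol_s = 0.4) {
  m <- match_event_pairs(data.frame(time_s = sort(det_times)),
                         data.frame(time_s = sort(true_times)), tol_s)
  tp <- m$n_same
  prec <- if (length(det_times)) tp / length(det_times) else 0
  rec <- if (length(true_times)) tp / length(true_times) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
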