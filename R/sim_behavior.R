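#' Simulate cued lever-pushing behaviour
#'
#' Generates a uniformly sampled lever-position trace plus the trial-event
#' table for one session. Each trial starts with a cue; rewarded-movement
#' (RM) trials contain a push crossing `push_threshold_mm` inside the task
#' window, with the reward delivered at the threshold crossing (delayed by
#' 1 s on `delay` trials, withheld on `omission` trials). Unrewarded
#' movements (UM) are sub-threshold push attempts inside the task window
#' and pushes during the ITI. At rest the lever jitters near 0 mm
#' (Ornstein-Uhlenbeck-like); pushes are smooth raised-cosine pulses.
#'
#' @param config a [sim_config()]
#' @return a list of class `behavior_record` with elements `lever`
#'   (`time_s`, `position_mm`), `trials` (`trial_id`, `cue_time_s`,
#'   `task_window_s`, `reward_time_s`, `punish_time_s`, `trial_end_s`,
#'   `trial_type`), `pushes` (ground-truth pushes with `label` RM/UM),
#'   `fs_hz`, `segment_s`, `push_threshold_mm`
#' @export
simulate_behavior <- function(config) {
  config <- validate_sim_config(config)
  set.seed(substream_seed(config$seed, "behavior"))
  fs <- config$fs_hz
  thr <- config$push_threshold_mm

  types <- c("standard", "delay", "omission", "cue_only", "punishment_only")
  p_extra <- config$trial_type_probs[c("delay", "omission", "cue_only",
                                       "punishment_only")]
  p_extra[is.na(p_extra)] <- 0
  type_p <- c(1 - sum(p_extra), p_extra)

  trials <- data.frame(trial_id = seq_len(config$n_trials),
                       cue_time_s = NA_real_,
                       task_window_s = config$task_window_s,
                       reward_time_s = NA_real_, punish_time_s = NA_real_,
                       trial_end_s = NA_real_,
                       trial_type = sample(types, config$n_trials,
                                           replace = TRUE, prob = type_p),
                       stringsAsFactors = FALSE)
  pushes <- list()
  cursor <- 3
  for (i in seq_len(config$n_trials)) {
    cue <- cursor
    trials$cue_time_s[i] <- cue
    tt <- trials$trial_type[i]
    push <- NULL
    if (tt %in% c("standard", "delay", "omission")) {
      hit <- if (tt == "standard") runif(1) < config$p_rm else TRUE
      if (hit) {
        reaction <- 0.4 + min(rlnorm(1, log(0.6), 0.4),
                              config$task_window_s - 2)
        onset <- cue + reaction
        dur <- runif(1, 0.4, 0.8)
        amp <- runif(1, max(1.2 * thr, thr + 0.3), 1.9 * thr)
        cross <- onset + (dur / pi) * asin(sqrt(thr / amp))
        push <- data.frame(trial_id = i, onset_s = onset,
                           peak_s = onset + dur / 2, cross_s = cross,
                           peak_mm = amp, duration_s = dur, label = "RM",
                           stringsAsFactors = FALSE)
        if (tt == "standard") {
          trials$reward_time_s[i] <- cross
          trials$trial_end_s[i] <- cross
        } else if (tt == "delay") {
          trials$reward_time_s[i] <- cross + 1
          trials$trial_end_s[i] <- cross + 1
        } else { # omission: threshold crossed, reward withheld
          trials$trial_end_s[i] <- cross
        }
      } else {
        if (runif(1) < config$p_push_fail) {
          reaction <- 0.4 + min(rlnorm(1, log(0.6), 0.4),
                                config$task_window_s - 2)
          onset <- cue + reaction
          dur <- runif(1, 0.4, 0.8)
          amp <- runif(1, 0.35, 0.85) * thr
          push <- data.frame(trial_id = i, onset_s = onset,
                             peak_s = onset + dur / 2, cross_s = NA_real_,
                             peak_mm = amp, duration_s = dur, label = "UM",
                             stringsAsFactors = FALSE)
        }
        trials$punish_time_s[i] <- cue + config$task_window_s
        trials$trial_end_s[i] <- trials$punish_time_s[i]
      }
    } else if (tt == "cue_only") {
      trials$trial_end_s[i] <- cue + config$cue_s
    } else { # punishment_only
      trials$punish_time_s[i] <- cue + config$cue_s
      trials$trial_end_s[i] <- trials$punish_time_s[i]
    }
    if (!is.null(push)) pushes[[length(pushes) + 1L]] <- push
    cursor <- trials$trial_end_s[i] +
      runif(1, config$iti_range_s[1], config$iti_range_s[2])
  }
  if (cursor + 2 > config$segment_s)
    stop(sprintf(paste0("segment_s (%g) too short for n_trials = %d ",
                        "(schedule needs %.1f s)"),
                 config$segment_s, config$n_trials, cursor + 2),
         call. = FALSE)

  # ITI pushes: UM by definition, placed in the gaps between trials with a
  # minimum 3.2-s spacing to keep pre-movement baselines clean
  if (config$iti_push_rate_hz > 0) {
    gaps <- cbind(trials$trial_end_s + 1,
                  c(trials$cue_time_s[-1], config$segment_s - 1) - 1)
    all_onsets <- unlist(lapply(pushes, function(p) p$onset_s))
    for (g in seq_len(nrow(gaps))) {
      len <- gaps[g, 2] - gaps[g, 1]
      if (len <= 0.8) next
      k <- rpois(1, config$iti_push_rate_hz * len)
      if (k == 0) next
      for (on in sort(runif(k, gaps[g, 1], gaps[g, 2] - 0.8))) {
        if (length(all_onsets) && min(abs(all_onsets - on)) < 3.2) next
        dur <- runif(1, 0.4, 0.8)
        amp <- runif(1, 0.4, 1.8) * thr
        pushes[[length(pushes) + 1L]] <-
          data.frame(trial_id = NA_integer_, onset_s = on,
                     peak_s = on + dur / 2,
                     cross_s = if (amp > thr)
                       on + (dur / pi) * asin(sqrt(thr / amp))
                     else NA_real_,
                     peak_mm = amp, duration_s = dur, label = "UM",
                     stringsAsFactors = FALSE)
        all_onsets <- c(all_onsets, on)
      }
    }
  }
  pushes <- if (length(pushes)) do.call(rbind, pushes) else
    data.frame(trial_id = integer(), onset_s = numeric(),
               peak_s = numeric(), cross_s = numeric(),
               peak_mm = numeric(), duration_s = numeric(),
               label = character(), stringsAsFactors = FALSE)
  pushes <- pushes[order(pushes$onset_s), , drop = FALSE]
  rownames(pushes) <- NULL
  pushes$push_id <- seq_len(nrow(pushes))

  # lever trace: OU-like rest jitter + raised-cosine pulses
  n <- sec_to_frames(config$segment_s, fs)
  tt_s <- (seq_len(n) - 1) / fs
  phi <- exp(-1 / (0.1 * fs))
  innov <- rnorm(n, 0, 0.04 * sqrt(1 - phi^2))
  pos <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  for (p in seq_len(nrow(pushes))) {
    on <- pushes$onset_s[p]; dur <- pushes$duration_s[p]
    sel <- tt_s >= on & tt_s <= on + dur
    pos[sel] <- pos[sel] +
      pushes$peak_mm[p] * sin(pi * (tt_s[sel] - on) / dur)^2
  }

  out <- list(lever = data.frame(time_s = tt_s, position_mm = pos),
              trials = trials, pushes = pushes, fs_hz = fs,
              segment_s = config$segment_s, push_threshold_mm = thr)
  class(out) <- "behavior_record"
  out
}
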