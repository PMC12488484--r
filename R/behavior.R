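#' Detect movement bouts in a lever trace
#'
#' Segments a uniformly sampled lever trace into movement bouts by
#' threshold crossing. Bouts separated by less than `merge_gap_s` are
#' considered one continuous movement and merged; a bout is marked
#' `excluded` when any other movement ends within `exclusion_window_s`
#' before its onset, so every retained bout has a clean pre-movement
#' baseline. When `threshold_mm` is `NULL` a robust resting threshold
#' (median + 3 MAD of the trace) is used; movements are sparse, so the
#' median and MAD estimate the resting distribution.
#'
#' @param lever data frame with `time_s` (strictly increasing, constant
#'   sampling interval) and `position_mm`
#' @param threshold_mm movement threshold separating rest from movement, or
#'   `NULL` for the robust automatic threshold
#' @param merge_gap_s gaps shorter than this are merged (default 0.5 s)
#' @param exclusion_window_s required movement-free window before each
#'   bout onset (default 3 s)
#' @return data frame of class `movement_bouts`: `onset_s`, `offset_s`,
#'   `peak_s`, `peak_mm`, `label` (`"unlabelled"` or `"excluded"`). Empty
#'   (zero-row) for an all-flat trace.
#' @export
detect_movement_bouts <- function(lever, threshold_mm = NULL,
                                  merge_gap_s = 0.5,
                                  exclusion_window_s = 3) {
  validate_lever(lever)
  pos <- lever$position_mm
  tt <- lever$time_s
  if (is.null(threshold_mm)) {
    threshold_mm <- stats::median(pos) + 3 * stats::mad(pos)
    if (stats::mad(pos) == 0 && max(pos) == min(pos))
      return(empty_bouts())
  }
  above <- pos > threshold_mm
  if (!any(above)) return(empty_bouts())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  iv <- merge_intervals(iv, tt, merge_gap_s)
  bouts <- data.frame(onset_s = tt[iv[, 1]], offset_s = tt[iv[, 2]],
                      peak_s = NA_real_, peak_mm = NA_real_,
                      label = "unlabelled", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(bouts))) {
    sel <- iv[i, 1]:iv[i, 2]
    k <- sel[which.max(pos[sel])]
    bouts$peak_s[i] <- tt[k]
    bouts$peak_mm[i] <- pos[k]
  }
  # clean-baseline rule: exclude a bout when another movement ends within
  # the exclusion window before its onset
  if (nrow(bouts) > 1) {
    for (i in 2:nrow(bouts)) {
      if (any(bouts$offset_s[seq_len(i - 1)] >
                bouts$onset_s[i] - exclusion_window_s))
        bouts$label[i] <- "excluded"
    }
  }
  class(bouts) <- c("movement_bouts", "data.frame")
  bouts
}

empty_bouts <- function() {
  b <- data.frame(onset_s = numeric(), offset_s = numeric(),
                  peak_s = numeric(), peak_mm = numeric(),
                  label = character(), stringsAsFactors = FALSE)
  class(b) <- c("movement_bouts", "data.frame")
  b
}

validate_lever <- function(lever) {
  stopifnot(is.data.frame(lever),
            all(c("time_s", "position_mm") %in% names(lever)))
  dt <- diff(lever$time_s)
  if (any(dt <= 0)) stop("lever time_s must be strictly increasing")
  if (nrow(lever) > 2 && diff(range(dt)) > 1e-6)
    stop("lever must be uniformly sampled (interval varies by > 1e-6 s)")
  invisible(lever)
}

# merge index intervals whose gap (in seconds) is below merge_gap_s;
# idempotent: merging already-merged intervals changes nothing
merge_intervals <- function(iv, tt, merge_gap_s) {
  if (nrow(iv) <= 1) return(iv)
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    gap <- tt[iv[i, 1]] - tt[out[nrow(out), 2]]
    if (gap < merge_gap_s) out[nrow(out), 2] <- iv[i, 2]
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

#' Label movement bouts as rewarded or unrewarded movements
#'
#' A bout is a rewarded movement (RM) when its peak exceeds
#' `push_threshold_mm` inside a trial's task window `[cue, cue +
#' task_window)`; it is an unrewarded movement (UM) when it stays below
#' threshold in the task window or occurs during the inter-trial interval.
#' Bouts flagged `excluded` by [detect_movement_bouts()] keep their flag.
#'
#' @param bouts output of [detect_movement_bouts()]
#' @param trials trial table with `trial_id`, `cue_time_s`,
#'   `task_window_s`
#' @param push_threshold_mm reward threshold (mm)
#' @return `bouts` with `label` set to `RM`/`UM`/`excluded` and a
#'   `trial_id` column (`NA` for ITI bouts)
#' @export
label_movements <- function(bouts, trials, push_threshold_mm = 1.5) {
  stopifnot(all(c("cue_time_s", "task_window_s") %in% names(trials)))
  trials <- trials[order(trials$cue_time_s), , drop = FALSE]
  if (nrow(trials) > 1 && any(diff(trials$cue_time_s) <= 0))
    stop("overlapping trials: cue times must be strictly increasing")
  # the task period ends at the trial outcome, so the effective window is
  # truncated at the next cue
  tw <- cbind(trials$cue_time_s,
              pmin(trials$cue_time_s + trials$task_window_s,
                   c(trials$cue_time_s[-1], Inf)))
  bouts$trial_id <- NA_integer_
  for (i in seq_len(nrow(bouts))) {
    if (bouts$label[i] == "excluded") next
    hit <- which(in_window(bouts$peak_s[i], tw[, 1], tw[, 2]))
    if (length(hit)) {
      bouts$trial_id[i] <- trials$trial_id[hit[1]]
      bouts$label[i] <- if (bouts$peak_mm[i] >= push_threshold_mm)
        "RM" else "UM"
    } else {
      bouts$label[i] <- "UM"  # ITI push
    }
  }
  bouts
}

#' Resample bout trajectories onto a common window
#'
#' Extracts the lever trajectory of each bout over
#' `[onset - pre_s, onset + post_s]` and resamples it to `n_points` by
#' linear interpolation, so trajectories are comparable across bouts.
#'
#' @param bouts labelled bouts
#' @param lever the lever trace
#' @param pre_s,post_s window around the bout onset (defaults 0.5 s before,
#'   2 s after)
#' @param n_points number of resampled points (default 64)
#' @return matrix bouts x `n_points`; rows of bouts whose window falls
#'   outside the trace are `NA`
#' @export
bout_trajectories <- function(bouts, lever, pre_s = 0.5, post_s = 2,
                              n_points = 64) {
  out <- matrix(NA_real_, nrow(bouts), n_points)
  for (i in seq_len(nrow(bouts))) {
    grid <- seq(bouts$onset_s[i] - pre_s, bouts$onset_s[i] + post_s,
                length.out = n_points)
    if (grid[1] < lever$time_s[1] ||
        grid[n_points] > lever$time_s[nrow(lever)]) next
    out[i, ] <- approx(lever$time_s, lever$position_mm, xout = grid)$y
  }
  out
}

#' Pearson correlation between two movement trajectories
#'
#' @param traj_a,traj_b equal-length resampled trajectories
#' @return Pearson r in `[-1, 1]`, or `NA` when either trajectory has zero
#'   variance (such pairs are excluded from binned curves)
#' @export
trajectory_correlation <- function(traj_a, traj_b) {
  safe_cor(traj_a, traj_b)
}

#' Behavioural session metrics
#'
#' Computes the session success rate (rewarded trials / cued trials), the
#' mean reaction time (cue to threshold crossing, over RM trials) and the
#' ITI push rate (UM bouts during the ITI per minute of ITI). The ITI runs
#' from the end of one trial (reward or punishment) to the next cue.
#'
#' @param trials trial table (with `reward_time_s`, `trial_end_s`)
#' @param bouts labelled bouts from [label_movements()]
#' @param lever lever trace, used to locate threshold crossings
#' @param push_threshold_mm reward threshold (mm)
#' @return list with `success_rate`, `mean_reaction_time_s`,
#'   `iti_push_rate_per_min`; all `NA` with `flag = "no_cued_trials"` when
#'   there are no cued trials
#' @export
session_metrics <- function(trials, bouts, lever,
                            push_threshold_mm = 1.5) {
  cued <- trials[trials$trial_type %in%
                   c("standard", "delay", "omission"), , drop = FALSE]
  if (nrow(cued) == 0)
    return(list(success_rate = NA_real_, mean_reaction_time_s = NA_real_,
                iti_push_rate_per_min = NA_real_, flag = "no_cued_trials"))
  success_rate <- mean(!is.na(cued$reward_time_s))

  rm_b <- bouts[bouts$label == "RM" & !is.na(bouts$trial_id), ,
                drop = FALSE]
  rts <- vapply(seq_len(nrow(rm_b)), function(i) {
    tr <- trials[trials$trial_id == rm_b$trial_id[i], ]
    sel <- lever$time_s >= rm_b$onset_s[i] &
      lever$time_s <= rm_b$offset_s[i] &
      lever$position_mm >= push_threshold_mm
    if (!any(sel)) return(NA_real_)
    min(lever$time_s[sel]) - tr$cue_time_s[1]
  }, numeric(1))
  mean_rt <- if (length(rts) && any(!is.na(rts)))
    mean(rts, na.rm = TRUE) else NA_real_

  # ITI spans: end of each trial to the next cue
  ends <- trials$trial_end_s[-nrow(trials)]
  nexts <- trials$cue_time_s[-1]
  iti_min <- sum(pmax(nexts - ends, 0)) / 60
  um_iti <- bouts$label == "UM" & is.na(bouts$trial_id)
  rate <- if (iti_min > 0) sum(um_iti) / iti_min else NA_real_

  list(success_rate = success_rate, mean_reaction_time_s = mean_rt,
       iti_push_rate_per_min = rate)
}
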