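#' Match calcium events between two ROIs ("same" vs "unique" peaks)
#'
#' Events of the two series occurring within `tol_s` of each other are
#' matched one-to-one ("same peaks"); unmatched events are "unique peaks".
#' Matching is greedy by ascending time difference, with ties broken by
#' the earlier event time and then by the first series, so the partition
#' is deterministic and each event participates in at most one match.
#'
#' @param a,b `event_series` (or data frames with `time_s`)
#' @param tol_s matching window in seconds (default 0.67)
#' @return list of class `pair_match`: `matches` (`i`, `j`, `dt_s` row
#'   indices into `a` and `b`), `n_same`, `n_unique_a`, `n_unique_b`,
#'   `frac_same_a`, `frac_same_b`
#' @export
match_event_pairs <- function(a, b, tol_s = 0.67) {
  if (tol_s < 0) stop("tol_s must be non-negative")
  ta <- a$time_s; tb <- b$time_s
  if (is.unsorted(ta) || is.unsorted(tb))
    stop("event times must be sorted (EventSeries invariant)")
  cand <- NULL
  if (length(ta) && length(tb)) {
    # event times are sorted, so candidates within tol_s come from a
    # narrow index band per event
    lo <- findInterval(ta - tol_s, tb) + 1L
    hi <- findInterval(ta + tol_s, tb)
    ii <- rep.int(seq_along(ta), pmax(hi - lo + 1L, 0L))
    jj <- unlist(lapply(seq_along(ta), function(i)
      if (hi[i] >= lo[i]) lo[i]:hi[i] else integer(0)))
    if (length(ii)) {
      dt <- abs(ta[ii] - tb[jj])
      keep <- dt <= tol_s
      cand <- data.frame(i = ii[keep], j = jj[keep], dt = dt[keep])
      cand <- cand[order(cand$dt, pmin(ta[cand$i], tb[cand$j]),
                         cand$i), , drop = FALSE]
    }
  }
  used_a <- logical(length(ta)); used_b <- logical(length(tb))
  mi <- integer(0); mj <- integer(0); mdt <- numeric(0)
  for (r in seq_len(NROW(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    mi <- c(mi, i); mj <- c(mj, j); mdt <- c(mdt, cand$dt[r])
  }
  n_same <- length(mi)
  out <- list(matches = data.frame(i = mi, j = mj, dt_s = mdt),
              n_same = n_same,
              n_unique_a = length(ta) - n_same,
              n_unique_b = length(tb) - n_same,
              frac_same_a = if (length(ta)) n_same / length(ta) else
                NA_real_,
              frac_same_b = if (length(tb)) n_same / length(tb) else
                NA_real_)
  class(out) <- "pair_match"
  out
}

#' Label calcium events by the movement they accompany
#'
#' An event is RM- or UM-related when it falls in the window from `pre_s`
#' before to `post_s` after a movement onset of that label (half-open
#' `[onset - pre_s, onset + post_s)`). When the windows of several onsets
#' contain the event (overlapping RM and UM windows), the nearest onset
#' wins and the collision is counted in the `collisions` attribute.
#'
#' @param events an `event_series`
#' @param onsets data frame with `onset_s` and `label` (`RM`/`UM`)
#' @param pre_s,post_s window around onset (defaults 0.33 s before,
#'   0.67 s after)
#' @return character vector, one of `"RM"`, `"UM"`, `"none"` per event
#' @export
label_events_by_movement <- function(events, onsets, pre_s = 0.33,
                                     post_s = 0.67) {
  lab <- rep("none", nrow(events))
  collisions <- 0L
  if (nrow(events) && NROW(onsets)) {
    for (e in seq_len(nrow(events))) {
      t <- events$time_s[e]
      hit <- which(in_window(t, onsets$onset_s - pre_s,
                             onsets$onset_s + post_s))
      if (length(hit) == 0) next
      if (length(hit) > 1) {
        collisions <- collisions + 1L
        hit <- hit[which.min(abs(onsets$onset_s[hit] - t))]
      }
      lab[e] <- onsets$label[hit[1]]
    }
  }
  attr(lab, "collisions") <- collisions
  lab
}

#' Fraction of "same" peaks per bouton, axon and mouse
#'
#' For every ordered pair of boutons on an axon, the fraction of the first
#' bouton's events matched by the second (`matched / total events of that
#' bouton`). Fractions are averaged over a bouton's pairings, then over
#' the boutons of an axon, then over axons, giving the per-mouse mean.
#' With `scope` `"RM"` or `"UM"` only events carrying that movement label
#' are considered (labels from [label_events_by_movement()]); boutons with
#' no in-scope events are excluded from the averages and counted in the
#' `n_excluded` field.
#'
#' @param events_by_roi named list of `event_series`, one per bouton ROI
#' @param rois ROI table (`roi_id`, `kind`, `axon_id`); only `bouton` rows
#'   are used, and axons need at least 2 boutons
#' @param scope `"all"` (default), `"RM"` or `"UM"`
#' @param onsets labelled movement onsets, required when `scope != "all"`
#' @param tol_s matching window (default 0.67 s)
#' @return list: `per_bouton` (`roi_id`, `axon_id`, `frac_same`),
#'   `per_axon` (`axon_id`, `frac_same`), `mouse_mean`, `n_excluded`
#' @export
same_peak_fraction <- function(events_by_roi, rois,
                               scope = c("all", "RM", "UM"),
                               onsets = NULL, tol_s = 0.67) {
  scope <- match.arg(scope)
  if (scope != "all" && is.null(onsets))
    stop("onsets required when scope != 'all'")
  b_rois <- rois[rois$kind == "bouton", , drop = FALSE]
  scoped <- lapply(events_by_roi[b_rois$roi_id], function(ev) {
    if (scope == "all" || nrow(ev) == 0) return(ev)
    ev[label_events_by_movement(ev, onsets) == scope, , drop = FALSE]
  })
  per_bouton <- list(); n_excluded <- 0L
  for (ax in unique(b_rois$axon_id)) {
    ids <- b_rois$roi_id[b_rois$axon_id == ax]
    if (length(ids) < 2) next
    counts <- vapply(scoped[ids], nrow, integer(1))
    ok <- counts > 0
    n_excluded <- n_excluded + sum(!ok)
    ids <- ids[ok]
    if (length(ids) < 2) next
    pm <- matrix(NA_real_, length(ids), length(ids))
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i) next
      m <- match_event_pairs(scoped[[ids[i]]], scoped[[ids[j]]], tol_s)
      pm[i, j] <- m$frac_same_a
      pm[j, i] <- m$frac_same_b
    }
    per_bouton[[ax]] <- data.frame(roi_id = ids, axon_id = ax,
                                   frac_same = rowMeans(pm, na.rm = TRUE),
                                   stringsAsFactors = FALSE)
  }
  per_bouton <- if (length(per_bouton)) do.call(rbind, per_bouton) else
    data.frame(roi_id = character(), axon_id = character(),
               frac_same = numeric(), stringsAsFactors = FALSE)
  rownames(per_bouton) <- NULL
  per_axon <- if (nrow(per_bouton))
    aggregate(frac_same ~ axon_id, per_bouton, mean) else
    data.frame(axon_id = character(), frac_same = numeric())
  list(per_bouton = per_bouton, per_axon = per_axon,
       mouse_mean = if (nrow(per_axon)) mean(per_axon$frac_same) else
         NA_real_,
       n_excluded = n_excluded)
}

#' Bouton-shaft (or any two-trace) correlation
#'
#' `mode = "segment"` is the Pearson correlation of the two full z-scored
#' traces. `mode = "peak_windows"` detects peaks on the first trace,
#' optionally keeps only peaks whose z amplitude lies in `amp_band`
#' (`c(lo, hi)`), and correlates the two traces over a 20-frame window per
#' peak (5 frames before to 15 frames after the peak, half-open), then
#' averages over peaks.
#'
#' @param bouton,shaft `dff_trace` objects (or numeric z traces with
#'   `fs_hz` supplied)
#' @param mode `"segment"` or `"peak_windows"`
#' @param amp_band optional length-2 amplitude band in z units
#' @param threshold_sd peak-detection threshold (default 1)
#' @param fs_hz sampling rate when passing bare numeric traces
#' @return correlation value, or `NA` (flagged via the `"n_peaks"`
#'   attribute) when no peak falls in the band
#' @export
shaft_bouton_correlation <- function(bouton, shaft,
                                     mode = c("segment", "peak_windows"),
                                     amp_band = NULL, threshold_sd = 1,
                                     fs_hz = NULL) {
  mode <- match.arg(mode)
  zb <- if (inherits(bouton, "dff_trace")) bouton$z else as.numeric(bouton)
  zs <- if (inherits(shaft, "dff_trace")) shaft$z else as.numeric(shaft)
  if (is.null(fs_hz) && inherits(bouton, "dff_trace"))
    fs_hz <- bouton$fs_hz
  if (mode == "segment") return(safe_cor(zb, zs))
  ev <- detect_events(zb, threshold_sd, fs_hz)
  if (!is.null(amp_band))
    ev <- ev[ev$amplitude_z >= amp_band[1] &
               ev$amplitude_z <= amp_band[2], , drop = FALSE]
  rs <- numeric(0)
  for (f in ev$frame) {
    idx <- (f - 5):(f + 14)
    idx <- idx[idx >= 1 & idx <= length(zb)]
    r <- safe_cor(zb[idx], zs[idx])
    if (!is.na(r)) rs <- c(rs, r)
  }
  out <- if (length(rs)) mean(rs) else NA_real_
  attr(out, "n_peaks") <- length(rs)
  out
}
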