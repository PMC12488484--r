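#' PCA embedding of boutons from trial-averaged activity
#'
#' Builds the 2M x N matrix whose columns are, per bouton, the
#' concatenated trial-averaged RM and UM activity (M timepoints per
#' condition over the [-1, 3) s window) and runs PCA across timepoints.
#' Each bouton is then a point in the space of the first three components
#' (its loadings), separating RM- from UM-preferring boutons. Component
#' signs are fixed so the loading of largest magnitude is positive.
#'
#' @param rm_means,um_means matrices boutons x M of trial-averaged z
#'   activity; rows must correspond (boutons lacking one condition are
#'   dropped beforehand by the caller)
#' @return list of class `bouton_embedding`: `scores` (N x 3 per-bouton
#'   principal coordinates, loadings scaled by component s.d.),
#'   `loadings`, `sdev`, `matrix_dim` (`c(2 * M, N)`)
#' @export
embed_boutons <- function(rm_means, um_means) {
  stopifnot(nrow(rm_means) == nrow(um_means),
            ncol(rm_means) == ncol(um_means))
  n <- nrow(rm_means)
  if (n < 3) stop("PCA embedding needs at least 3 boutons")
  x <- rbind(t(rm_means), t(um_means))  # 2M x N
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(3, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k))
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  # principal coordinates: loadings scaled by the component s.d., so
  # zero-variance components place all boutons at the origin
  scores <- sweep(rot, 2, p$sdev[seq_len(k)], "*")
  out <- list(scores = scores, loadings = rot, sdev = p$sdev,
              matrix_dim = dim(x))
  class(out) <- "bouton_embedding"
  out
}

#' Per-trial trajectories of the first three population PCs
#'
#' Runs PCA on the continuous segment (frames x boutons z matrix), keeps
#' the first three component time courses, and cuts one trajectory per
#' movement onset over [-1, 3) s. Onsets without a full window are
#' dropped.
#'
#' @param z_mat frames x boutons matrix of z-scored activity
#' @param onsets data frame with `onset_s` and `label` (`RM`/`UM`)
#' @param fs_hz sampling rate
#' @param pre_s,post_s trajectory window (defaults 1 s before, 3 s after)
#' @return list: `trajectories` (list of T x 3 matrices), `labels`,
#'   `pc_series` (frames x 3)
#' @export
pc_trajectories <- function(z_mat, onsets, fs_hz, pre_s = 1, post_s = 3) {
  if (ncol(z_mat) < 3) stop("PCA needs at least 3 boutons")
  pcs <- stats::prcomp(z_mat, center = TRUE, scale. = FALSE)$x[, 1:3,
                                                               drop = FALSE]
  nf <- sec_to_frames(pre_s + post_s, fs_hz)
  trajs <- list(); labs <- character(0)
  for (r in seq_len(nrow(onsets))) {
    start0 <- sec_to_frames(onsets$onset_s[r] - pre_s, fs_hz)
    idx <- start0 + seq_len(nf)
    if (idx[1] < 1 || idx[nf] > nrow(pcs)) next
    trajs[[length(trajs) + 1L]] <- pcs[idx, , drop = FALSE]
    labs <- c(labs, onsets$label[r])
  }
  list(trajectories = trajs, labels = labs, pc_series = pcs)
}

#' Summed frame-wise distance between two PC trajectories
#'
#' Euclidean distance in PC space computed frame by frame and summed over
#' the trajectory.
#'
#' @param a,b T x k trajectory matrices of equal dimension
#' @return non-negative scalar
#' @export
trajectory_distance <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sum(sqrt(rowSums((a - b)^2)))
}

#' Trajectory selectivity index of a single trial
#'
#' For an RM trial the index is `(d_UM - d_RM) / (d_RM + d_UM)`, where
#' `d_RM`/`d_UM` are the summed frame-wise distances of the trial
#' trajectory to the mean RM and mean UM trajectories; for a UM trial the
#' roles are swapped. The index is 1 when the trial trajectory coincides
#' with the mean trajectory of its own type, -1 when it coincides with
#' the mean of the opposite type, and 0 when equidistant. Undefined (NA)
#' only when both distances are 0.
#'
#' @param traj T x 3 single-trial trajectory
#' @param mean_rm,mean_um mean RM and UM trajectories
#' @param label trial label, `"RM"` or `"UM"`
#' @return list: `index`, `d_rm`, `d_um`
#' @export
selectivity_index <- function(traj, mean_rm, mean_um,
                              label = c("RM", "UM")) {
  label <- match.arg(label)
  d_rm <- trajectory_distance(traj, mean_rm)
  d_um <- trajectory_distance(traj, mean_um)
  idx <- if (d_rm + d_um == 0) NA_real_
  else if (label == "RM") (d_um - d_rm) / (d_rm + d_um)
  else (d_rm - d_um) / (d_rm + d_um)
  list(index = idx, d_rm = d_rm, d_um = d_um)
}

#' Selectivity indices for all trials of a segment
#'
#' Computes mean RM and UM trajectories (element-wise averages of the
#' single-trial trajectories) and the per-trial selectivity index.
#'
#' @param trajs output of [pc_trajectories()]
#' @return data frame of class `selectivity_result`: `trial`, `label`,
#'   `d_rm`, `d_um`, `index`; `NULL` with a warning when either condition
#'   has no trials
#' @export
trajectory_selectivity <- function(trajs) {
  labs <- trajs$labels
  if (!any(labs == "RM") || !any(labs == "UM")) {
    warning("need at least one RM and one UM trial for mean trajectories")
    return(NULL)
  }
  mean_traj <- function(sel)
    Reduce(`+`, trajs$trajectories[sel]) / sum(sel)
  m_rm <- mean_traj(labs == "RM")
  m_um <- mean_traj(labs == "UM")
  res <- lapply(seq_along(labs), function(i)
    selectivity_index(trajs$trajectories[[i]], m_rm, m_um, labs[i]))
  out <- data.frame(trial = seq_along(labs), label = labs,
                    d_rm = vapply(res, `[[`, numeric(1), "d_rm"),
                    d_um = vapply(res, `[[`, numeric(1), "d_um"),
                    index = vapply(res, `[[`, numeric(1), "index"),
                    stringsAsFactors = FALSE)
  class(out) <- c("selectivity_result", "data.frame")
  out
}

#' Bin a statistic against movement-trajectory correlation
#'
#' Averages `y` within the standard movement-correlation bins (-0.2-0,
#' 0-0.2, ..., 0.8-1). Empty bins are reported with `NA` mean and
#' `n = 0`, never as 0.
#'
#' @param x movement-trajectory correlations per pair
#' @param y the statistic per pair
#' @param breaks bin edges (default `seq(-0.2, 1, 0.2)`)
#' @return data frame of class `binned_curve`: `bin_lo`, `bin_hi`,
#'   `mean`, `n`
#' @export
binned_curve <- function(x, y, breaks = seq(-0.2, 1, by = 0.2)) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    mean = NA_real_, n = 0L)
  for (k in seq_len(nb)) {
    sel <- bin == k
    if (any(sel)) {
      out$mean[k] <- mean(y[sel])
      out$n[k] <- sum(sel)
    }
  }
  class(out) <- c("binned_curve", "data.frame")
  out
}

#' Population activity-pattern correlation vs movement similarity
#'
#' Concatenates the aligned activity of all responsive boutons into one
#' population vector per trial, correlates the vectors of every trial
#' pair, and bins the pairwise activity correlations by the corresponding
#' movement-trajectory correlations. Pairs with a zero-variance vector are
#' skipped and counted.
#'
#' @param act_mat trials x features matrix (concatenated per-trial aligned
#'   activity of all responsive boutons, same order per trial)
#' @param traj_mat trials x points matrix of resampled movement
#'   trajectories
#' @return list: `pairs` (`i`, `j`, `move_r`, `act_r`), `curve` (a
#'   [binned_curve()]), `n_skipped`
#' @export
pattern_correlation_curve <- function(act_mat, traj_mat) {
  stopifnot(nrow(act_mat) == nrow(traj_mat), nrow(act_mat) >= 2)
  n <- nrow(act_mat)
  pr <- t(combn(n, 2))
  move_r <- numeric(nrow(pr)); act_r <- numeric(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    move_r[k] <- safe_cor(traj_mat[pr[k, 1], ], traj_mat[pr[k, 2], ])
    act_r[k] <- safe_cor(act_mat[pr[k, 1], ], act_mat[pr[k, 2], ])
  }
  keep <- !is.na(act_r) & !is.na(move_r)
  list(pairs = data.frame(i = pr[, 1], j = pr[, 2], move_r = move_r,
                          act_r = act_r)[keep, ],
       curve = binned_curve(move_r[keep], act_r[keep]),
       n_skipped = sum(!keep))
}

#' Fraction of activated-ensemble difference between two trials
#'
#' `|a - b| / (0.5 * (a + b))` for activated-bouton counts `a` and `b`:
#' 0 when the counts are equal, at most 2, and undefined when both are 0.
#'
#' @param a,b activated-bouton counts of the two trials
#' @return value in `[0, 2]`, `NA` when `a = b = 0`
#' @export
ensemble_difference <- function(a, b) {
  ifelse(a + b == 0, NA_real_, abs(a - b) / (0.5 * (a + b)))
}

#' Activated-ensemble difference vs movement similarity
#'
#' For every trial pair, the fraction of activated-ensemble difference
#' ([ensemble_difference()]) is binned against the movement-trajectory
#' correlation. Undefined pairs (both counts 0) are skipped and counted.
#'
#' @param counts per-trial activated-bouton counts
#' @param traj_mat trials x points movement-trajectory matrix
#' @return list: `pairs`, `curve`, `n_skipped`
#' @export
ensemble_difference_curve <- function(counts, traj_mat) {
  stopifnot(length(counts) == nrow(traj_mat), length(counts) >= 2)
  pr <- t(combn(length(counts), 2))
  move_r <- vapply(seq_len(nrow(pr)), function(k)
    safe_cor(traj_mat[pr[k, 1], ], traj_mat[pr[k, 2], ]), numeric(1))
  dval <- ensemble_difference(counts[pr[, 1]], counts[pr[, 2]])
  keep <- !is.na(dval) & !is.na(move_r)
  list(pairs = data.frame(i = pr[, 1], j = pr[, 2], move_r = move_r,
                          diff = dval)[keep, ],
       curve = binned_curve(move_r[keep], dval[keep]),
       n_skipped = sum(!keep))
}

#' Count activated responsive boutons per trial
#'
#' A responsive bouton is "activated" in a trial when it has at least one
#' detected event in the window `[onset, onset + window_s)` after that
#' trial's movement onset.
#'
#' @param events_by_roi named list of `event_series`
#' @param responsive_ids ROI ids of the responsive boutons
#' @param onsets_s per-trial movement onset times
#' @param window_s activation window after onset (default 3 s)
#' @return integer vector of activated counts, one per trial
#' @export
activated_counts <- function(events_by_roi, responsive_ids, onsets_s,
                             window_s = 3) {
  vapply(onsets_s, function(on) {
    sum(vapply(responsive_ids, function(id) {
      ev <- events_by_roi[[id]]
      !is.null(ev) && any(in_window(ev$time_s, on, on + window_s))
    }, logical(1)))
  }, integer(1))
}

#' Within-axon response heterogeneity
#'
#' Fraction of an axon's responsive boutons carrying the minority RM/UM
#' label. `both`-category boutons count toward the dominant side
#' (`both_policy = "dominant"`, the default) or are excluded;
#' unresponsive boutons never enter the denominator. Ties give 0.5 with a
#' tie flag.
#'
#' @param categories character vector of bouton categories along one axon
#' @param both_policy `"dominant"` or `"exclude"`
#' @return list: `heterogeneity` (in `[0, 0.5]`, `NA` when no responsive
#'   bouton), `dominant`, `tie`, `n_responsive`
#' @export
axon_heterogeneity <- function(categories,
                               both_policy = c("dominant", "exclude")) {
  both_policy <- match.arg(both_policy)
  n_rm <- sum(categories == "RM_only")
  n_um <- sum(categories == "UM_only")
  n_both <- if (both_policy == "dominant") sum(categories == "both") else 0L
  n_resp <- n_rm + n_um + n_both
  if (n_resp == 0)
    return(list(heterogeneity = NA_real_, dominant = NA_character_,
                tie = FALSE, n_responsive = 0L))
  if (n_rm == 0 && n_um == 0)  # all 'both': no minority label
    return(list(heterogeneity = 0, dominant = "both", tie = FALSE,
                n_responsive = n_resp))
  if (n_rm == n_um)
    return(list(heterogeneity = 0.5, dominant = "tie", tie = TRUE,
                n_responsive = n_resp))
  dominant <- if (n_rm > n_um) "RM" else "UM"
  minority <- min(n_rm, n_um)
  list(heterogeneity = minority / n_resp, dominant = dominant,
       tie = FALSE, n_responsive = n_resp)
}

#' Axon-pair activity correlations and the 0.7 split
#'
#' Pearson correlations of all axon pairs from the per-segment z traces,
#' with the conventional split into highly correlated (r > 0.7) and less
#' correlated pairs.
#'
#' @param axon_z_mat frames x axons matrix of z-scored axon traces
#' @param high_cut split point (default 0.7)
#' @return list: `pairs` (`axon_a`, `axon_b`, `r`, `high`), `frac_high`
#' @export
axon_pair_correlation <- function(axon_z_mat, high_cut = 0.7) {
  stopifnot(ncol(axon_z_mat) >= 2)
  ids <- colnames(axon_z_mat)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(axon_z_mat)))
  pr <- t(combn(ncol(axon_z_mat), 2))
  r <- vapply(seq_len(nrow(pr)), function(k)
    safe_cor(axon_z_mat[, pr[k, 1]], axon_z_mat[, pr[k, 2]]), numeric(1))
  pairs <- data.frame(axon_a = ids[pr[, 1]], axon_b = ids[pr[, 2]], r = r,
                      high = r > high_cut, stringsAsFactors = FALSE)
  list(pairs = pairs, frac_high = mean(pairs$high, na.rm = TRUE))
}
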