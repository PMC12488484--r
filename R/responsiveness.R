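#' Align a z-scored trace to movement onsets
#'
#' Cuts one window per onset, spanning `pre_s` before to `post_s` after
#' the onset (half-open, `round((pre_s + post_s) * fs)` frames; the 1 s
#' before onset serves as the baseline). Onsets whose window is not fully
#' inside the segment are dropped and counted.
#'
#' @param z numeric z-scored trace (or a `dff_trace`)
#' @param onsets_s movement onset times (s)
#' @param fs_hz sampling rate; taken from the `dff_trace` when omitted
#' @param pre_s,post_s window extent (defaults 1 s before, 3 s after)
#' @return list of class `aligned_tensor`: `mat` (trials x frames),
#'   `mean_trace`, `time_s` (frame times relative to onset), `pre_s`,
#'   `fs_hz`, `n_dropped`; `mat` has zero rows when no onset has a full
#'   window
#' @export
align_to_onsets <- function(z, onsets_s, fs_hz = NULL, pre_s = 1,
                            post_s = 3) {
  if (inherits(z, "dff_trace")) {
    if (is.null(fs_hz)) fs_hz <- z$fs_hz
    z <- z$z
  }
  nf <- sec_to_frames(pre_s + post_s, fs_hz)
  n <- length(z)
  rows <- list(); dropped <- 0L
  for (on in onsets_s) {
    start0 <- sec_to_frames(on - pre_s, fs_hz)  # 0-based start
    idx <- start0 + seq_len(nf)
    if (idx[1] < 1 || idx[nf] > n) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- z[idx]
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, nf)
  out <- list(mat = mat,
              mean_trace = if (nrow(mat)) colMeans(mat) else rep(NA_real_,
                                                                 nf),
              time_s = (seq_len(nf) - 1) / fs_hz - pre_s,
              pre_s = pre_s, fs_hz = fs_hz, n_dropped = dropped)
  class(out) <- "aligned_tensor"
  out
}

#' Bouton responsiveness from a trial-averaged trace
#'
#' A bouton is responsive when the peak of its trial-averaged z trace in
#' the window `peak_window` (relative to onset, half-open) minus the 5th
#' percentile of the whole averaged trace exceeds `criterion_sd` (z
#' units; the default 0.9 is 90% of the segment s.d.).
#'
#' @param aligned an `aligned_tensor` (or a bare mean trace with `time_s`)
#' @param peak_window window for the peak search, seconds relative to
#'   onset (default `c(-0.2, 3)`)
#' @param criterion_sd responsiveness criterion in z units (default 0.9)
#' @return logical; `NA` when the tensor is empty
#' @export
classify_bouton_responsive <- function(aligned,
                                       peak_window = c(-0.2, 3),
                                       criterion_sd = 0.9) {
  mt <- aligned$mean_trace
  if (all(is.na(mt))) return(NA)
  sel <- in_window(aligned$time_s, peak_window[1], peak_window[2])
  peak <- max(mt[sel])
  p5 <- as.numeric(quantile(mt, 0.05, type = 7))
  (peak - p5) > criterion_sd
}

#' Axon responsiveness with a histogram-derived threshold
#'
#' Pools the trial-averaged peak responses of all axons of a mouse, in RM
#' and UM trials separately; the response is each axon's aligned-mean peak
#' minus the 5th percentile of its mean trace. Histograms with bin width
#' `bin_sd` give the modal bin of each distribution (ties take the lowest
#' bin); the threshold is the mean of the two modal bin centres, capped at
#' `cap_sd`. With fewer than `min_axons` axons the histogram is
#' unreliable and the cap is used directly. An axon is responsive in a
#' condition when its response exceeds the threshold.
#'
#' @param resp_rm,resp_um numeric vectors: per-axon responses (peak minus
#'   5th percentile) in RM and UM trials
#' @param bin_sd histogram bin width in z units (default 0.1)
#' @param cap_sd threshold cap in z units (default 1)
#' @param min_axons minimum axons for the histogram route (default 10)
#' @return list: `threshold`, `resp_rm`, `resp_um` (logical vectors)
#' @export
classify_axons <- function(resp_rm, resp_um, bin_sd = 0.1, cap_sd = 1,
                           min_axons = 10) {
  stopifnot(length(resp_rm) == length(resp_um))
  if (length(resp_rm) < min_axons) {
    thr <- cap_sd
  } else {
    mode_centre <- function(x) {
      lo <- floor(min(x) / bin_sd) * bin_sd
      breaks <- seq(lo, max(x) + bin_sd, by = bin_sd)
      counts <- tabulate(findInterval(x, breaks), length(breaks) - 1)
      # which.max takes the lowest tied bin
      breaks[which.max(counts)] + bin_sd / 2
    }
    thr <- min(mean(c(mode_centre(resp_rm), mode_centre(resp_um))),
               cap_sd)
  }
  list(threshold = thr, resp_rm = resp_rm > thr, resp_um = resp_um > thr)
}

#' Combine RM and UM responsiveness into a category
#'
#' `(TRUE, FALSE)` is `RM_only`, `(FALSE, TRUE)` `UM_only`, `(TRUE, TRUE)`
#' `both`, `(FALSE, FALSE)` `unresponsive`. The RM-responsive grouping
#' used elsewhere is `RM_only` plus `both`.
#'
#' @param resp_rm,resp_um logical vectors
#' @return character vector of categories; `NA` where either flag is `NA`
#' @export
categorize_response <- function(resp_rm, resp_um) {
  out <- ifelse(resp_rm & resp_um, "both",
                ifelse(resp_rm, "RM_only",
                       ifelse(resp_um, "UM_only", "unresponsive")))
  out[is.na(resp_rm) | is.na(resp_um)] <- NA_character_
  out
}

response_categories <- c("RM_only", "UM_only", "both", "unresponsive")

#' Category fate table between two learning stages
#'
#' Cross-tabulates unit categories at the early stage (rows) against the
#' late stage (columns). Row-normalised proportions give the fate of each
#' early category; column-normalised proportions give the origin of each
#' late category. Empty rows/columns are flagged rather than propagated as
#' NaN.
#'
#' @param early,late data frames with `unit_id` and `category`; the same
#'   unit ids must appear in both
#' @return list of class `fate_table`: `counts` (4 x 4), `fate`
#'   (row-normalised), `origin` (column-normalised), `empty_rows`,
#'   `empty_cols`
#' @export
track_fate <- function(early, late) {
  miss <- c(setdiff(early$unit_id, late$unit_id),
            setdiff(late$unit_id, early$unit_id))
  if (length(miss))
    stop("unit ids not shared between stages: ",
         paste(head(miss, 5), collapse = ", "))
  late_cat <- late$category[match(early$unit_id, late$unit_id)]
  f <- function(x) factor(x, levels = response_categories)
  counts <- table(early = f(early$category), late = f(late_cat))
  rs <- rowSums(counts); cs <- colSums(counts)
  fate <- sweep(counts, 1, ifelse(rs == 0, NA, rs), "/")
  origin <- sweep(counts, 2, ifelse(cs == 0, NA, cs), "/")
  out <- list(counts = unclass(counts), fate = unclass(fate),
              origin = unclass(origin),
              empty_rows = names(rs)[rs == 0],
              empty_cols = names(cs)[cs == 0])
  class(out) <- "fate_table"
  out
}

#' Delay-reward modulation of a bouton
#'
#' A responsive bouton is delay-reward modulated when the peak time of its
#' trial-averaged trace in reward-delay trials lags the RM-trial peak time
#' by more than `shift_s` (default 0.93 s); such boutons track the reward
#' rather than the movement. Also reports the mean activity in the
#' post-reward windows used for omission analysis: 1.67-2.33 s after onset
#' in delay trials and 0.67-1.33 s in omission trials.
#'
#' @param rm_aligned,delay_aligned,omission_aligned `aligned_tensor`s of
#'   the same bouton (omission may be `NULL`)
#' @param shift_s modulation criterion on the peak-time shift (s)
#' @param responsive logical; when `FALSE` classification is skipped
#' @return list: `delay_modulated`, `peak_shift_s`, `omission_means`
#'   (`delay_window`, `omission_window`)
#' @export
classify_reward_modulated <- function(rm_aligned, delay_aligned,
                                      omission_aligned = NULL,
                                      shift_s = 0.93, responsive = TRUE) {
  if (!isTRUE(responsive))
    return(list(delay_modulated = NA, peak_shift_s = NA_real_,
                omission_means = NULL))
  pk_time <- function(al) al$time_s[which.max(al$mean_trace)]
  shift <- pk_time(delay_aligned) - pk_time(rm_aligned)
  win_mean <- function(al, lo, hi) {
    if (is.null(al)) return(NA_real_)
    mean(al$mean_trace[in_window(al$time_s, lo, hi)])
  }
  list(delay_modulated = shift > shift_s, peak_shift_s = shift,
       omission_means = list(
         delay_window = win_mean(delay_aligned, 1.67, 2.33),
         omission_window = win_mean(omission_aligned, 0.67, 1.33)))
}
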