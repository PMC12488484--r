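#' Simulate bouton and shaft fluorescence with ground truth
#'
#' Generates raw fluorescence traces for every bouton and its parent axon
#' shaft, with a per-event ground truth. Each axon draws a response
#' category from `category_mix`; each of its boutons conforms to the axon
#' category with probability `shared_event_fraction` and otherwise re-draws
#' from the mix, so one parameter controls both the shared/unique event
#' split and the within-axon category heterogeneity. Movement-locked units
#' emit a transient on each matching movement onset with probability
#' `p_respond`; the transient is axon-wide ("shared", expressed by the
#' shaft and by every category-compatible bouton) with probability
#' `shared_event_fraction` and bouton-unique otherwise. Movement-unlocked
#' (`unresponsive`) units emit Poisson events at `event_rate_hz` with the
#' same shared/unique split. Transients are difference-of-exponential
#' kernels with lognormal amplitudes centred on `snr` noise s.d.; noise is
#' Gaussian, independent across ROIs and temporally smoothed at
#' `noise_smooth_s`; a slow sinusoid-plus-linear drift (≤ `drift_frac` of
#' baseline) keeps the sliding-percentile baseline honest.
#'
#' @param behavior a `behavior_record` from [simulate_behavior()]
#' @param config the [sim_config()] used to generate `behavior`
#' @return a list of class `fluor_set`: `fluor` (frames x ROIs matrix of
#'   raw fluorescence, columns named by ROI id), `rois` (`roi_id`, `kind`,
#'   `axon_id`, `position_um`), `fs_hz`, and `truth` with `boutons`
#'   (`roi_id`, `axon_id`, `category`, `axon_category`) and `events`
#'   (`roi_id`, `time_s`, `amplitude`, `shared`, `event_uid`)
#' @export
simulate_activity <- function(behavior, config) {
  config <- validate_sim_config(config)
  stopifnot(inherits(behavior, "behavior_record"))
  set.seed(substream_seed(config$seed, "activity"))
  fs <- config$fs_hz
  n <- nrow(behavior$lever)
  t_end <- behavior$segment_s
  s <- config$shared_event_fraction
  cats <- c("RM_only", "UM_only", "both", "unresponsive")

  onsets <- behavior$pushes[, c("onset_s", "label")]
  compatible <- function(cat) switch(cat,
    RM_only = onsets$onset_s[onsets$label == "RM"],
    UM_only = onsets$onset_s[onsets$label == "UM"],
    both = onsets$onset_s,
    unresponsive = numeric(0))

  draw_amp <- function(k) {
    if (config$snr <= 0) rep(0, k)
    else rlnorm(k, log(config$snr), config$amp_sdlog)
  }

  roi_rows <- list(); bouton_rows <- list(); event_rows <- list()
  streams <- list()  # per ROI: event times + amplitudes (dF/F units later)
  uid <- 0L
  L <- config$turnover$axon_length_um

  for (ax in seq_len(config$n_axons)) {
    axon_id <- sprintf("a%03d", ax)
    cat_a <- sample(cats, 1, prob = config$category_mix)

    # axon-wide (shared) event stream; each shared event remembers the
    # movement onset it locks to (NA for unlocked events)
    comp_a <- compatible(cat_a)
    if (cat_a == "unresponsive") {
      k <- rpois(1, s * config$event_rate_hz * (t_end - 4))
      sh_on <- rep(NA_real_, k)
      sh_t <- sort(runif(k, 2, t_end - 2))
    } else {
      sh_on <- comp_a[runif(length(comp_a)) < config$p_respond * s]
      sh_t <- sh_on + runif(length(sh_on), 0.05, 0.35)
    }
    keep_t <- sh_t < t_end - 1
    sh_t <- sh_t[keep_t]; sh_on <- sh_on[keep_t]
    sh_amp <- draw_amp(length(sh_t))
    sh_lab <- if (cat_a == "unresponsive") rep("none", length(sh_t)) else {
      lab <- character(length(sh_t))
      if (length(sh_t)) {
        near <- vapply(sh_t, function(x)
          which.min(abs(onsets$onset_s - x)), integer(1))
        lab <- onsets$label[near]
      }
      lab
    }
    sh_uid <- if (length(sh_t)) uid + seq_along(sh_t) else integer(0)
    uid <- uid + length(sh_t)

    # shaft expresses the full shared stream
    shaft_id <- sprintf("%s_shaft", axon_id)
    streams[[shaft_id]] <- data.frame(time_s = sh_t, amplitude = sh_amp,
                                      shared = rep(TRUE, length(sh_t)),
                                      event_uid = sh_uid)
    roi_rows[[length(roi_rows) + 1L]] <-
      data.frame(roi_id = shaft_id, kind = "shaft", axon_id = axon_id,
                 position_um = NA_real_, stringsAsFactors = FALSE)

    for (b in seq_len(config$boutons_per_axon)) {
      roi_id <- sprintf("%s_b%02d", axon_id, b)
      cat_b <- if (runif(1) < s) cat_a else
        sample(cats, 1, prob = config$category_mix)

      # shared events whose movement label is compatible with this bouton
      keep <- if (cat_b == "both") sh_lab %in% c("RM", "UM")
        else if (cat_b == "unresponsive") sh_lab == "none"
        else sh_lab == sub("_only", "", cat_b)
      bt <- sh_t[keep]
      ba <- sh_amp[keep] *
        pmax(0.2, 1 + config$amp_jitter * rnorm(sum(keep)))
      bu <- sh_uid[keep]
      bs <- rep(TRUE, sum(keep))

      # bouton-unique events: at compatible onsets not already carrying a
      # shared event this bouton expresses, emit a unique event with a
      # probability chosen so the per-onset response probability equals
      # p_respond and the per-bouton shared fraction equals s
      if (cat_b == "unresponsive") {
        k <- rpois(1, (1 - s) * config$event_rate_hz * (t_end - 4))
        ut <- runif(k, 2, t_end - 2)
      } else {
        comp_b <- compatible(cat_b)
        free <- setdiff(comp_b, sh_on[keep])
        ps <- config$p_respond * s
        q <- if (ps >= 1) 0 else config$p_respond * (1 - s) / (1 - ps)
        hitu <- free[runif(length(free)) < q]
        ut <- hitu + runif(length(hitu), 0.05, 0.35)
      }
      ut <- ut[ut < t_end - 1]
      if (length(ut)) {
        bt <- c(bt, ut); ba <- c(ba, draw_amp(length(ut)))
        bu <- c(bu, uid + seq_along(ut)); bs <- c(bs, rep(FALSE, length(ut)))
        uid <- uid + length(ut)
      }
      o <- order(bt)
      streams[[roi_id]] <- data.frame(time_s = bt[o], amplitude = ba[o],
                                      shared = bs[o], event_uid = bu[o])
      roi_rows[[length(roi_rows) + 1L]] <-
        data.frame(roi_id = roi_id, kind = "bouton", axon_id = axon_id,
                   position_um = runif(1, 0, L), stringsAsFactors = FALSE)
      bouton_rows[[length(bouton_rows) + 1L]] <-
        data.frame(roi_id = roi_id, axon_id = axon_id, category = cat_b,
                   axon_category = cat_a, stringsAsFactors = FALSE)
    }
  }

  rois <- do.call(rbind, roi_rows)
  rownames(rois) <- NULL

  # transient kernel (difference of exponentials, unit peak)
  kt <- seq(0, 6 * config$tau_decay_s, by = 1 / fs)
  kern <- exp(-kt / config$tau_decay_s) - exp(-kt / config$tau_rise_s)
  kern <- kern / max(kern)

  # temporally smoothed unit-variance noise, independent across ROIs;
  # circular FFT convolution of white noise with a Gaussian kernel is
  # stationary, so the wrap-around is statistically harmless
  m <- max(1L, sec_to_frames(config$noise_smooth_s, fs))
  gk <- exp(-0.5 * (seq(-3 * m, 3 * m)) ^ 2 / m ^ 2)
  gk <- gk / sqrt(sum(gk ^ 2))  # unit variance after convolution
  nroi <- nrow(rois)
  kpad <- numeric(n)
  kpad[1:length(gk)] <- gk
  kf <- stats::fft(kpad)
  # pack two real columns per complex FFT: linearity keeps the real and
  # imaginary parts independent after convolution with a real kernel
  npair <- ceiling(nroi / 2)
  white <- matrix(rnorm(n * 2 * npair), n, 2 * npair)
  zc <- white[, seq_len(npair) * 2 - 1] + 1i * white[, seq_len(npair) * 2]
  sm <- stats::mvfft(stats::mvfft(zc) * kf, inverse = TRUE) / n
  noise <- matrix(0, n, 2 * npair)
  noise[, seq_len(npair) * 2 - 1] <- Re(sm)
  noise[, seq_len(npair) * 2] <- Im(sm)
  noise <- noise[, seq_len(nroi), drop = FALSE]

  fluor <- matrix(NA_real_, n, nroi, dimnames = list(NULL, rois$roi_id))
  tt_s <- (seq_len(n) - 1) / fs
  for (j in seq_len(nroi)) {
    ev <- streams[[rois$roi_id[j]]]
    sig <- numeric(n)
    if (nrow(ev)) {
      f0idx <- sec_to_frames(ev$time_s, fs) + 1L
      for (e in seq_len(nrow(ev))) {
        idx <- f0idx[e]:min(n, f0idx[e] + length(kern) - 1L)
        sig[idx] <- sig[idx] + ev$amplitude[e] * kern[seq_along(idx)]
      }
    }
    period <- runif(1, 120, 200)
    drift <- config$drift_frac *
      (0.4 * sin(2 * pi * tt_s / period + runif(1, 0, 2 * pi)) +
         0.4 * (tt_s / t_end - 0.5))
    f0_true <- config$baseline_f * (1 + drift)
    fluor[, j] <- f0_true *
      (1 + config$noise_dff * (sig + noise[, j]))
  }

  events <- do.call(rbind, lapply(names(streams), function(id) {
    ev <- streams[[id]]
    if (!nrow(ev)) return(NULL)
    cbind(data.frame(roi_id = id, stringsAsFactors = FALSE), ev)
  }))
  rownames(events) <- NULL

  out <- list(fluor = fluor, rois = rois, fs_hz = fs,
              truth = list(boutons = do.call(rbind, bouton_rows),
                           events = events))
  class(out) <- "fluor_set"
  out
}
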