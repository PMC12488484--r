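#' Simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-data
#' generators ([simulate_behavior()], [simulate_activity()],
#' [simulate_bouton_maps()], [simulate_dataset()]). Defaults emulate a
#' single imaging session of the cued lever-pushing task: ~15-Hz frame
#' rate, 4-min continuous segments, a 1.5-mm push threshold, GCaMP-like
#' transients shared across the boutons of an axon plus bouton-unique
#' events at a controlled fraction, and session-to-session bouton
#' formation/elimination with optional spatial clustering.
#'
#' @param n_mice number of mice (datasets are generated per mouse)
#' @param n_axons axons per mouse
#' @param boutons_per_axon boutons per axon
#' @param fs_hz imaging frame rate (Hz)
#' @param segment_s duration of the continuous imaged segment (s)
#' @param n_trials number of cued trials
#' @param p_rm probability that a cued trial ends in a rewarded,
#'   threshold-crossing push
#' @param task_window_s task period after the cue (s)
#' @param cue_s cue duration (s)
#' @param iti_range_s length-2 range for the inter-trial interval (s)
#' @param trial_type_probs named numeric: proportions of `delay`,
#'   `omission`, `cue_only`, `punishment_only` trials (remainder standard)
#' @param push_threshold_mm lever threshold for a rewarded push (mm)
#' @param p_push_fail probability an unrewarded cued trial still contains a
#'   sub-threshold push attempt
#' @param iti_push_rate_hz rate of lever pushes during the ITI
#' @param shared_event_fraction probability a transient is shared by all
#'   boutons of its axon (vs bouton-unique)
#' @param event_rate_hz rate of transients for movement-unlocked units
#' @param p_respond probability a movement-locked unit emits a transient on
#'   a matching movement
#' @param snr transient peak amplitude in units of the noise s.d.
#' @param amp_sdlog lognormal spread of transient amplitudes around `snr`
#' @param amp_jitter per-bouton multiplicative amplitude jitter for shared
#'   events
#' @param tau_rise_s,tau_decay_s indicator kinetics of the
#'   difference-of-exponentials transient kernel (s)
#' @param noise_smooth_s temporal correlation scale of the additive noise
#'   (Gaussian kernel s.d., s)
#' @param noise_dff baseline noise s.d. on the dF/F scale
#' @param drift_frac slow drift amplitude as a fraction of baseline
#'   fluorescence
#' @param baseline_f baseline raw fluorescence (a.u., keeps traces positive)
#' @param category_mix named proportions of `RM_only`, `UM_only`, `both`,
#'   `unresponsive` axon categories; must sum to 1
#' @param turnover list with `p_form`, `p_elim` (per-session rates),
#'   `cluster_sigma_um` (Gaussian cluster s.d. for formed boutons, or
#'   `NULL` for uniform placement), `axon_length_um`, `n_sessions`
#' @param seed master seed; every generator derives a named substream from
#'   it
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_mice = 1,
                       n_axons = 20,
                       boutons_per_axon = 5,
                       fs_hz = 15,
                       segment_s = 240,
                       n_trials = 20,
                       p_rm = 0.6,
                       task_window_s = 10,
                       cue_s = 0.5,
                       iti_range_s = c(3, 6),
                       trial_type_probs = c(delay = 0, omission = 0,
                                            cue_only = 0,
                                            punishment_only = 0),
                       push_threshold_mm = 1.5,
                       p_push_fail = 0.8,
                       iti_push_rate_hz = 0.05,
                       shared_event_fraction = 0.7,
                       event_rate_hz = 0.05,
                       p_respond = 0.8,
                       snr = 8,
                       amp_sdlog = 0.25,
                       amp_jitter = 0,
                       tau_rise_s = 0.05,
                       tau_decay_s = 1.5,
                       noise_smooth_s = 1,
                       noise_dff = 0.02,
                       drift_frac = 0.1,
                       baseline_f = 100,
                       category_mix = c(RM_only = 0.35, UM_only = 0.35,
                                        both = 0.15, unresponsive = 0.15),
                       turnover = list(p_form = 0.1, p_elim = 0.1,
                                       cluster_sigma_um = NULL,
                                       axon_length_um = 100,
                                       n_sessions = 5),
                       seed = 1) {
  cfg <- list(n_mice = n_mice, n_axons = n_axons,
              boutons_per_axon = boutons_per_axon, fs_hz = fs_hz,
              segment_s = segment_s, n_trials = n_trials, p_rm = p_rm,
              task_window_s = task_window_s, cue_s = cue_s,
              iti_range_s = iti_range_s,
              trial_type_probs = trial_type_probs,
              push_threshold_mm = push_threshold_mm,
              p_push_fail = p_push_fail,
              iti_push_rate_hz = iti_push_rate_hz,
              shared_event_fraction = shared_event_fraction,
              event_rate_hz = event_rate_hz, p_respond = p_respond,
              snr = snr, amp_sdlog = amp_sdlog, amp_jitter = amp_jitter,
              tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
              noise_smooth_s = noise_smooth_s, noise_dff = noise_dff,
              drift_frac = drift_frac, baseline_f = baseline_f,
              category_mix = category_mix, turnover = turnover,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
      config_error(field, "must be a probability in [0, 1]")
  }
  chk_pos <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      config_error(field, "must be a positive number")
  }
  chk_pos(cfg$fs_hz, "fs_hz")
  chk_pos(cfg$segment_s, "segment_s")
  if (!is.numeric(cfg$snr) || cfg$snr < 0) config_error("snr", "must be >= 0")
  chk_prob(cfg$p_rm, "p_rm")
  chk_prob(cfg$shared_event_fraction, "shared_event_fraction")
  chk_prob(cfg$p_respond, "p_respond")
  chk_prob(cfg$p_push_fail, "p_push_fail")
  chk_prob(cfg$trial_type_probs, "trial_type_probs")
  if (sum(cfg$trial_type_probs) > 1)
    config_error("trial_type_probs", "must sum to at most 1")
  cm <- cfg$category_mix
  need <- c("RM_only", "UM_only", "both", "unresponsive")
  if (!all(need %in% names(cm)))
    config_error("category_mix",
                 "must name RM_only, UM_only, both, unresponsive")
  chk_prob(cm, "category_mix")
  if (abs(sum(cm) - 1) > 1e-9)
    config_error("category_mix", "must sum to 1 (tolerance 1e-9)")
  tv <- cfg$turnover
  chk_prob(tv$p_form, "turnover$p_form")
  chk_prob(tv$p_elim, "turnover$p_elim")
  chk_pos(tv$axon_length_um, "turnover$axon_length_um")
  if (!is.null(tv$cluster_sigma_um) && tv$cluster_sigma_um <= 0)
    config_error("turnover$cluster_sigma_um",
                 "must be > 0 when clustering is enabled")
  if (tv$n_sessions < 2)
    config_error("turnover$n_sessions", "must be >= 2")
  for (f in c("n_axons", "boutons_per_axon", "n_trials"))
    if (cfg[[f]] < 1) config_error(f, "must be >= 1")
  cfg
}
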