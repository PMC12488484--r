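test_that("identical config and seed give identical datasets", {
  cfg <- tiny_cfg(seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$behavior$lever, b$behavior$lever)
  expect_identical(a$behavior$trials, b$behavior$trials)
  expect_identical(a$activity$fluor, b$activity$fluor)
  expect_identical(a$activity$truth, b$activity$truth)
  expect_identical(a$structure$maps, b$structure$maps)
})

test_that("degenerate probabilities produce the expected corner cases", {
  # all trials rewarded, no ITI pushes -> only RM pushes in ground truth
  beh <- simulate_behavior(tiny_cfg(p_rm = 1, n_trials = 10,
                                    iti_push_rate_hz = 0,
                                    segment_s = 200))
  expect_equal(sum(beh$pushes$label == "RM"), 10)
  expect_equal(sum(beh$pushes$label == "UM"), 0)

  # frozen map: no formation, no elimination
  ms <- simulate_bouton_maps(tiny_cfg(
    turnover = list(p_form = 0, p_elim = 0, cluster_sigma_um = NULL,
                    axon_length_um = 100, n_sessions = 4)))
  per_session <- split(ms$maps[c("axon_id", "bouton_id", "position_um")],
                       ms$maps$session)
  for (k in 2:4) expect_equal(per_session[[k]], per_session[[1]],
                              ignore_attr = TRUE)

  # total elimination at session 2
  ms2 <- simulate_bouton_maps(tiny_cfg(
    turnover = list(p_form = 0, p_elim = 1, cluster_sigma_um = NULL,
                    axon_length_um = 100, n_sessions = 2)))
  s1 <- ms2$maps$bouton_id[ms2$maps$session == 1]
  s2 <- ms2$maps$bouton_id[ms2$maps$session == 2]
  expect_length(intersect(s1, s2), 0)
})

test_that("realized RM fraction matches the binomial expectation", {
  fr <- vapply(1:20, function(seed) {
    beh <- simulate_behavior(tiny_cfg(n_trials = 200, p_rm = 0.6,
                                      segment_s = 2600,
                                      iti_push_rate_hz = 0, seed = seed))
    cued <- beh$trials$trial_type %in% c("standard", "delay", "omission")
    mean(!is.na(beh$trials$reward_time_s[cued]))
  }, numeric(1))
  tol <- 3 * sqrt(0.6 * 0.4 / 200)
  expect_true(all(abs(fr - 0.6) <= tol))
})

test_that("realized formation rate matches the binomial expectation", {
  rates <- vapply(1:100, function(seed) {
    ms <- simulate_bouton_maps(sim_config(
      n_axons = 50, boutons_per_axon = 10,
      turnover = list(p_form = 0.3, p_elim = 0, cluster_sigma_um = NULL,
                      axon_length_um = 100, n_sessions = 2),
      seed = seed))
    s1 <- ms$maps$bouton_id[ms$maps$session == 1]
    s2 <- ms$maps$bouton_id[ms$maps$session == 2]
    length(setdiff(s2, s1)) / length(s1)
  }, numeric(1))
  se <- sqrt(0.3 * 0.7 / 500)
  expect_lt(abs(mean(rates) - 0.3), 3 * se / sqrt(100) + 0.002)
  expect_true(all(abs(rates - 0.3) < 6 * se))
})

test_that("ground truth is internally consistent", {
  sim <- simulate_dataset(tiny_cfg(seed = 3))
  ev <- sim$activity$truth$events
  expect_true(all(ev$shared %in% c(TRUE, FALSE)))
  # shared events appear on > 1 ROI under a pure category mix; unique ones
  # on exactly one
  dup <- table(ev$event_uid)
  expect_true(all(dup[as.character(ev$event_uid[!ev$shared])] == 1))
  # per session pair, formed and eliminated sets are disjoint
  for (ch in sim$structure$truth$changes)
    expect_length(intersect(ch$formed, ch$eliminated), 0)
})

test_that("fully shared axons give boutons the shaft's event list", {
  cfg <- unlocked_cfg(shared = 1, events = 40, seed = 5)
  act <- simulate_activity(simulate_behavior(cfg), cfg)
  ev <- split(act$truth$events$time_s, act$truth$events$roi_id)
  for (ax in unique(act$rois$axon_id)) {
    shaft <- ev[[paste0(ax, "_shaft")]]
    for (b in act$rois$roi_id[act$rois$axon_id == ax &
                                act$rois$kind == "bouton"])
      expect_equal(ev[[b]], shaft)
  }
})

test_that("snr = 0 yields traces with no transient structure", {
  cfg <- unlocked_cfg(shared = 0.7, events = 60, seed = 6, snr = 0)
  act <- simulate_activity(simulate_behavior(cfg), cfg)
  z <- compute_dff(act$fluor[, 1], cfg$fs_hz)$z
  expect_lt(max(abs(z)), 6)  # pure noise + drift, no 8-sd transients
})

test_that("event-detection F1 is non-decreasing in snr", {
  f1 <- vapply(c(1, 4, 8), function(snr) {
    cfg <- unlocked_cfg(shared = 0.7, n_axons = 4, boutons = 2,
                        segment_s = 1200, events = 80, seed = 9,
                        snr = snr)
    act <- simulate_activity(simulate_behavior(cfg), cfg)
    mean(vapply(act$rois$roi_id[act$rois$kind == "bouton"], function(id) {
      det <- detect_events(compute_dff(act$fluor[, id], cfg$fs_hz))
      tru <- act$truth$events$time_s[act$truth$events$roi_id == id]
      event_f1(det$time_s, tru)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(f1) >= -0.01))
  expect_gt(f1[3], f1[1])
})

test_that("configuration errors name the offending field", {
  expect_error(tiny_cfg(p_rm = 1.2), "p_rm")
  expect_error(tiny_cfg(fs_hz = 0), "fs_hz")
  expect_error(tiny_cfg(category_mix = c(RM_only = 0.5, UM_only = 0.5,
                                         both = 0.1, unresponsive = 0)),
               "category_mix")
  expect_error(tiny_cfg(turnover = list(p_form = 0.1, p_elim = 0.1,
                                        cluster_sigma_um = -1,
                                        axon_length_um = 100,
                                        n_sessions = 3)),
               "cluster_sigma_um")
  expect_error(simulate_behavior(tiny_cfg(segment_s = 60, n_trials = 50)),
               "too short")
})
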