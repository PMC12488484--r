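test_that("flat traces yield no movement bouts", {
  lever <- data.frame(time_s = seq(0, 10, by = 0.05),
                      position_mm = 0)
  expect_equal(nrow(detect_movement_bouts(lever)), 0)
  expect_equal(nrow(detect_movement_bouts(lever, threshold_mm = 0.5)), 0)
})

test_that("bouts separated by less than 500 ms are merged", {
  # pulses above threshold over 1.0-1.2 s and 1.5-1.7 s: gap 0.3 s
  fs <- 20
  tt <- seq(0, 5, by = 1 / fs)
  pos <- as.numeric(tt > 0.99 & tt < 1.21) + (tt > 1.49 & tt < 1.71)
  b <- detect_movement_bouts(data.frame(time_s = tt, position_mm = pos),
                             threshold_mm = 0.5)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset_s, 1.0)
  expect_equal(b$offset_s, 1.7)
})

test_that("a movement within the preceding 3 s excludes a bout", {
  fs <- 20
  tt <- seq(0, 12, by = 1 / fs)
  pos <- as.numeric(tt > 2.99 & tt < 4.01) + (tt > 6.49 & tt < 7.01)
  b <- detect_movement_bouts(data.frame(time_s = tt, position_mm = pos),
                             threshold_mm = 0.5)
  expect_equal(nrow(b), 2)
  expect_equal(b$label, c("unlabelled", "excluded"))  # gap 2.5 s < 3 s
})

test_that("movement merging is idempotent", {
  set.seed(7)
  for (rep in 1:20) {
    iv <- matrix(sort(sample(1:400, 12)), ncol = 2, byrow = TRUE)
    tt <- seq(0, 40, by = 0.1)
    m1 <- boutondyn:::merge_intervals(iv, tt, 0.5)
    m2 <- boutondyn:::merge_intervals(m1, tt, 0.5)
    expect_identical(m1, m2)
  }
})

test_that("RM/UM labelling follows threshold and task window", {
  trials <- data.frame(trial_id = 1:2, cue_time_s = c(5, 40),
                       task_window_s = 10)
  lever <- pulse_lever(c(6, 20, 41), c(2.0, 2.0, 1.0), total_s = 60)
  b <- detect_movement_bouts(lever, threshold_mm = 0.3)
  b <- label_movements(b, trials, push_threshold_mm = 1.5)
  expect_equal(b$label, c("RM", "UM", "UM"))   # task+above, ITI, task+below
  expect_equal(b$trial_id, c(1L, NA_integer_, 2L))
})

test_that("overlapping trials are rejected", {
  trials <- data.frame(trial_id = 1:2, cue_time_s = c(5, 5),
                       task_window_s = 10)
  b <- detect_movement_bouts(pulse_lever(6, 2, total_s = 30),
                             threshold_mm = 0.3)
  expect_error(label_movements(b, trials), "overlapping")
})

test_that("trajectory correlation matches the Pearson oracle", {
  lever <- pulse_lever(c(5, 15), c(2, 2.5), dur = c(0.4), total_s = 30)
  b <- detect_movement_bouts(lever, threshold_mm = 0.3)
  tr <- bout_trajectories(b, lever)
  expect_equal(trajectory_correlation(tr[1, ], tr[1, ]), 1.0)
  expect_equal(trajectory_correlation(tr[1, ], -tr[1, ]), -1.0)
  # two triangular pulses of different widths vs direct cor()
  t1 <- approx(c(0, 10, 30, 64), c(0, 2, 0, 0), xout = 1:64)$y
  t2 <- approx(c(0, 20, 40, 64), c(0, 1.5, 0, 0), xout = 1:64)$y
  expect_equal(trajectory_correlation(t1, t2), cor(t1, t2))
  expect_true(is.na(trajectory_correlation(rep(1, 64), t1)))
})

test_that("session metrics recover constructed latencies and rates", {
  # two rewarded trials with threshold crossings 0.5 s and 1.5 s post cue
  fs <- 20
  trials <- data.frame(trial_id = 1:2, cue_time_s = c(5, 25),
                       task_window_s = 10,
                       reward_time_s = c(5.5, 26.5),
                       punish_time_s = NA_real_,
                       trial_end_s = c(5.5, 26.5),
                       trial_type = "standard")
  tt <- seq(0, 40, by = 1 / fs)
  pos <- numeric(length(tt))
  # ramps reaching the 1.5-mm threshold exactly at the stated times
  ramp <- function(on, cross) {
    sel <- tt >= on & tt <= cross + 0.5
    pos[sel] <<- approx(c(on, cross, cross + 0.5), c(0.31, 1.5, 0),
                        xout = tt[sel])$y
  }
  ramp(5.3, 5.5); ramp(26.3, 26.5)
  lever <- data.frame(time_s = tt, position_mm = pos)
  b <- label_movements(detect_movement_bouts(lever, threshold_mm = 0.3),
                       trials, push_threshold_mm = 1.5)
  m <- session_metrics(trials, b, lever, push_threshold_mm = 1.5)
  expect_equal(m$success_rate, 1.0)
  expect_equal(m$mean_reaction_time_s, mean(c(0.5, 1.5)), tolerance = 0.06)
  expect_equal(m$iti_push_rate_per_min, 0)
})

test_that("zero cued trials flags undefined metrics", {
  trials <- data.frame(trial_id = 1, cue_time_s = 5, task_window_s = 1,
                       reward_time_s = NA_real_, punish_time_s = 5.5,
                       trial_end_s = 5.5, trial_type = "cue_only")
  m <- session_metrics(trials, boutondyn:::empty_bouts(),
                       pulse_lever(numeric(0), numeric(0)))
  expect_true(is.na(m$success_rate))
  expect_equal(m$flag, "no_cued_trials")
})

test_that("synthgen movement labels are recovered from the lever trace", {
  cfg <- tiny_cfg(n_trials = 15, segment_s = 400, seed = 8,
                  iti_range_s = c(4, 6))
  beh <- simulate_behavior(cfg)
  b <- detect_movement_bouts(beh$lever, threshold_mm = 0.3)
  b <- label_movements(b, beh$trials, cfg$push_threshold_mm)
  b <- b[b$label %in% c("RM", "UM"), ]
  tr <- beh$pushes
  expect_equal(nrow(b), nrow(tr))
  # onset within one merge window, identical labels
  o <- vapply(b$onset_s, function(x) which.min(abs(tr$onset_s - x)),
              integer(1))
  expect_true(all(abs(b$onset_s - tr$onset_s[o]) < 0.5))
  expect_equal(b$label, tr$label[o])
  # every RM bout's peak crosses threshold inside its trial's task window
  rm_b <- b[b$label == "RM", ]
  for (i in seq_len(nrow(rm_b))) {
    trl <- beh$trials[beh$trials$trial_id == rm_b$trial_id[i], ]
    expect_gte(rm_b$peak_mm[i], cfg$push_threshold_mm)
    expect_true(rm_b$peak_s[i] >= trl$cue_time_s &&
                  rm_b$peak_s[i] < trl$cue_time_s + trl$task_window_s)
  }
})
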