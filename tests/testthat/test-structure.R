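mk_maps <- function(...) {
  # list(session = list(axon = c(bouton ids))) -> maps data frame
  layout <- list(...)
  do.call(rbind, lapply(seq_along(layout), function(s) {
    do.call(rbind, lapply(names(layout[[s]]), function(ax) {
      ids <- layout[[s]][[ax]]
      if (!length(ids)) return(NULL)
      data.frame(session = s, axon_id = ax, bouton_id = ids,
                 position_um = seq(5, by = 7, length.out = length(ids)),
                 stringsAsFactors = FALSE)
    }))
  }))
}

test_that("turnover counts follow set arithmetic", {
  maps <- mk_maps(list(a1 = c("b1", "b2", "b3")),
                  list(a1 = c("b2", "b3", "b4", "b5")))
  tr <- compute_turnover(maps, 1, 2, 100)
  expect_equal(tr$per_axon$n_persistent, 2)
  expect_equal(tr$per_axon$n_formed, 2)
  expect_equal(tr$per_axon$n_eliminated, 1)
  expect_equal(tr$per_axon$elimination_rate, 1 / 3)
  expect_equal(tr$per_axon$density, 4 / 100)

  same <- compute_turnover(mk_maps(list(a1 = c("b1", "b2")),
                                   list(a1 = c("b1", "b2"))), 1, 2, 100)
  expect_equal(same$per_axon$n_formed, 0)
  expect_equal(same$per_axon$n_eliminated, 0)

  gone <- compute_turnover(mk_maps(list(a1 = c("b1", "b2")),
                                   list(a1 = character(0))), 1, 2, 100)
  expect_equal(gone$per_axon$elimination_rate, 1.0)
})

test_that("turnover conservation identities hold on simulated maps", {
  for (seed in 1:5) {
    ms <- simulate_bouton_maps(tiny_cfg(seed = seed))
    sessions <- sort(unique(ms$maps$session))
    for (k in seq_len(length(sessions) - 1)) {
      tr <- compute_turnover(ms$maps, sessions[k], sessions[k + 1],
                             ms$axon_length_um)
      expect_equal(tr$per_axon$n_persistent + tr$per_axon$n_eliminated,
                   tr$per_axon$n_prev)
      expect_equal(tr$per_axon$n_persistent + tr$per_axon$n_formed,
                   tr$per_axon$n_curr)
      # density rises iff formation exceeds elimination
      expect_equal(tr$per_axon$density > tr$per_axon$n_prev /
                     ms$axon_length_um,
                   tr$per_axon$n_formed > tr$per_axon$n_eliminated)
    }
  }
})

test_that("turnover matches generator ground truth exactly", {
  ms <- simulate_bouton_maps(sim_config(
    n_axons = 15, boutons_per_axon = 8,
    turnover = list(p_form = 0.25, p_elim = 0.2, cluster_sigma_um = NULL,
                    axon_length_um = 120, n_sessions = 4), seed = 31))
  for (ss in 2:4) {
    tr <- compute_turnover(ms$maps, ss - 1, ss, 120)
    truth <- ms$truth$changes
    for (ax in tr$per_axon$axon_id) {
      ch <- truth[[sprintf("%s_s%d", ax, ss)]]
      row <- tr$per_axon[tr$per_axon$axon_id == ax, ]
      expect_equal(row$n_formed, length(ch$formed))
      expect_equal(row$n_eliminated, length(ch$eliminated))
    }
  }
})

test_that("position-based matching agrees with id matching on rigid maps", {
  ms <- simulate_bouton_maps(tiny_cfg(seed = 32))
  t_id <- compute_turnover(ms$maps, 1, 2, ms$axon_length_um, match = "id")
  t_pos <- compute_turnover(ms$maps, 1, 2, ms$axon_length_um,
                            match = "position", tol_um = 0.01)
  expect_equal(t_pos$per_axon$n_persistent, t_id$per_axon$n_persistent)
})

test_that("survival curves count the formed cohort and never increase", {
  maps <- mk_maps(list(a1 = "b0"),
                  list(a1 = c("b0", "b1", "b2", "b3", "b4")),
                  list(a1 = c("b0", "b2", "b3", "b4")),
                  list(a1 = c("b0", "b2", "b4")))
  sv <- survival_curve(maps, 2)
  expect_equal(sv$survival, c(0.75, 0.5))
  expect_equal(attr(sv, "cohort_size"), 4)
  # frozen maps: full survival
  frozen <- mk_maps(list(a1 = "b0"), list(a1 = c("b0", "b1")),
                    list(a1 = c("b0", "b1")), list(a1 = c("b0", "b1")))
  expect_equal(survival_curve(frozen, 2)$survival, c(1, 1))
  # empty cohort flagged
  sv0 <- survival_curve(frozen, 3)
  expect_true(isTRUE(attr(sv0, "empty_cohort")))
  # monotone on random simulated maps
  for (seed in 1:5) {
    ms <- simulate_bouton_maps(tiny_cfg(seed = seed))
    sv <- survival_curve(ms$maps, 2)
    if (nrow(sv)) expect_true(all(diff(sv$survival) <= 0))
  }
})

test_that("nearest-neighbour distances match their definition", {
  expect_equal(nnd_values(c(0, 5)), c(5, 5))
  set.seed(33)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1), 0, 100)
    bf <- vapply(seq_along(p), function(i) min(abs(p[-i] - p[i])),
                 numeric(1))
    expect_equal(sort(nnd_values(p)), sort(bf))
  }
})

test_that("the NND permutation test is reproducible and validated", {
  pos <- list(a1 = c(5, 8, 40, 80), a2 = c(10, 14, 60))
  r1 <- nnd_analysis(pos, 100, n_shuffles = 200, seed = 9)
  r2 <- nnd_analysis(pos, 100, n_shuffles = 200, seed = 9)
  expect_identical(r1$band_hi, r2$band_hi)
  expect_identical(r1$significant, r2$significant)
  expect_true(all(diff(r1$obs_cdf) >= 0))
  expect_true(all(r1$obs_cdf >= 0 & r1$obs_cdf <= 1))
  expect_true(all(r1$band_lo <= r1$band_hi + 1e-12))
  expect_error(nnd_analysis(pos, 100, n_shuffles = 200), "seed")
  expect_warning(nnd_analysis(pos, 100, n_shuffles = 50, seed = 1),
                 "n_shuffles")
  # singleton axons are skipped
  r3 <- nnd_analysis(c(pos, list(a3 = 42)), 100, n_shuffles = 200,
                     seed = 9)
  expect_equal(r3$n_skipped, 1L)
  # permutation variant runs and keeps CDF shape
  r4 <- nnd_analysis(pos, 100, n_shuffles = 200, seed = 9,
                     shuffle = "permute")
  expect_true(all(diff(r4$shuffle_mean) >= -1e-12))
})

test_that("clustered formations are detected against the shuffle null", {
  mk_pos <- function(sigma, seed) {
    cfg <- sim_config(n_axons = 30, boutons_per_axon = 10,
                      turnover = list(p_form = 0.3, p_elim = 0.1,
                                      cluster_sigma_um = sigma,
                                      axon_length_um = 100,
                                      n_sessions = 2), seed = seed)
    ms <- simulate_bouton_maps(cfg)
    s1 <- ms$maps[ms$maps$session == 1, ]
    s2 <- ms$maps[ms$maps$session == 2, ]
    lapply(split(s2, s2$axon_id), function(df)
      df$position_um[!df$bouton_id %in% s1$bouton_id])
  }
  r_cl <- nnd_analysis(mk_pos(10, 44), 100, n_shuffles = 1000, seed = 45)
  expect_true(r_cl$significant)
  rng <- r_cl$exceedance_range_um
  expect_true(rng[1] <= 30 && rng[2] >= 5)
  r_un <- nnd_analysis(mk_pos(NULL, 44), 100, n_shuffles = 1000,
                       seed = 45)
  expect_false(r_un$significant)
})
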