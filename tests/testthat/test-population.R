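test_that("the embedding matrix is 2M x N and separates tuned groups", {
  set.seed(15)
  M <- 60; N <- 50
  rm_means <- matrix(0, N, M); um_means <- matrix(0, N, M)
  grp <- rep(c("RM", "UM"), each = N / 2)
  bump <- bump_trace(M, 30, 3)
  for (i in seq_len(N)) {
    if (grp[i] == "RM") rm_means[i, ] <- bump else um_means[i, ] <- bump
    rm_means[i, ] <- rm_means[i, ] + rnorm(M, 0, 0.1)
    um_means[i, ] <- um_means[i, ] + rnorm(M, 0, 0.1)
  }
  emb <- embed_boutons(rm_means, um_means)
  expect_equal(emb$matrix_dim, c(2 * M, N))
  sc <- emb$scores
  c_rm <- colMeans(sc[grp == "RM", ]); c_um <- colMeans(sc[grp == "UM", ])
  spread <- mean(c(apply(sc[grp == "RM", ], 2, sd),
                   apply(sc[grp == "UM", ], 2, sd)))
  expect_gt(sqrt(sum((c_rm - c_um)^2)), 3 * spread)
  # sign convention: largest-magnitude loading positive
  for (j in 1:3) expect_gt(sc[which.max(abs(sc[, j])), j], 0)
  # identical boutons collapse to one point
  same <- matrix(rep(bump, 5), 5, byrow = TRUE)
  emb2 <- embed_boutons(same, same)
  expect_lt(max(apply(emb2$scores, 2, sd)), 1e-8)
  expect_error(embed_boutons(same[1:2, ], same[1:2, ]), "at least 3")
})

test_that("selectivity index hits its analytic endpoints", {
  set.seed(16)
  tpts <- 60
  mean_rm <- matrix(rnorm(tpts * 3), tpts, 3)
  mean_um <- matrix(rnorm(tpts * 3), tpts, 3)
  expect_equal(selectivity_index(mean_rm, mean_rm, mean_um, "RM")$index, 1)
  expect_equal(selectivity_index(mean_um, mean_rm, mean_um, "RM")$index, -1)
  expect_equal(selectivity_index(mean_um, mean_rm, mean_um, "UM")$index, 1)
  # equidistant: reflect through the midpoint
  mid <- (mean_rm + mean_um) / 2
  expect_equal(selectivity_index(mid, mean_rm, mean_um, "RM")$index, 0)
  # degenerate: both distances zero
  expect_true(is.na(selectivity_index(mean_rm, mean_rm, mean_rm,
                                      "RM")$index))
})

test_that("selectivity index is bounded and antisymmetric", {
  set.seed(17)
  for (rep in 1:30) {
    tr <- matrix(rnorm(45), 15, 3)
    m1 <- matrix(rnorm(45), 15, 3); m2 <- matrix(rnorm(45), 15, 3)
    i_rm <- selectivity_index(tr, m1, m2, "RM")$index
    i_um <- selectivity_index(tr, m1, m2, "UM")$index
    expect_lte(abs(i_rm), 1)
    expect_equal(i_rm, -i_um)
    # swapping the means flips the sign
    expect_equal(selectivity_index(tr, m2, m1, "RM")$index, -i_rm)
  }
})

test_that("trajectory selectivity recovers trial structure end to end", {
  set.seed(18)
  fs <- 15; n <- 3000
  onsets <- data.frame(onset_s = seq(20, 180, by = 16),
                       label = rep(c("RM", "UM"), length.out = 11))
  z <- matrix(rnorm(n * 6, 0, 0.3), n, 6)
  for (r in seq_len(nrow(onsets))) {
    f <- round(onsets$onset_s[r] * fs)
    cols <- if (onsets$label[r] == "RM") 1:3 else 4:6
    for (cc in cols) z[f:(f + 20), cc] <- z[f:(f + 20), cc] + 3
  }
  trajs <- pc_trajectories(z, onsets, fs)
  sel <- trajectory_selectivity(trajs)
  expect_true(all(sel$index > 0))   # every trial closer to its own mean
  expect_true(all(abs(sel$index) <= 1))
})

test_that("top-3 PCs explain rank-3 data exactly", {
  set.seed(19)
  z <- matrix(rnorm(600 * 3), 600, 3) %*% matrix(rnorm(3 * 10), 3, 10)
  p <- prcomp(z, center = TRUE)
  expect_lt(sum(p$sdev[-(1:3)]^2) / sum(p$sdev^2), 1e-8)
  # and the PC trajectories pipeline accepts it
  trajs <- pc_trajectories(z, data.frame(onset_s = 20, label = "RM"), 15)
  expect_equal(dim(trajs$trajectories[[1]]), c(60L, 3L))
})

test_that("binned curves use the standard bins and flag empty ones", {
  bc <- binned_curve(c(-0.1, 0.1, 0.15, 0.95), c(1, 2, 4, 8))
  expect_equal(nrow(bc), 6)
  expect_equal(bc$mean[1], 1)
  expect_equal(bc$mean[2], 3)
  expect_equal(bc$n[3], 0)
  expect_true(is.na(bc$mean[3]))
  expect_equal(bc$mean[6], 8)
})

test_that("pattern correlation tracks movement similarity", {
  set.seed(20)
  n_tr <- 24
  traj <- matrix(rnorm(n_tr * 64), n_tr)
  ident <- matrix(rep(rnorm(100), n_tr), n_tr, byrow = TRUE)
  pc <- pattern_correlation_curve(ident + rnorm(n_tr * 100, 0, 1e-8), traj)
  occ <- pc$curve$n > 0
  expect_true(all(abs(pc$curve$mean[occ] - 1) < 1e-6))
  # independent activity: occupied bin means near 0
  indep <- matrix(rnorm(n_tr * 400), n_tr)
  pc2 <- pattern_correlation_curve(indep, traj)
  expect_true(all(abs(pc2$curve$mean[pc2$curve$n > 5]) < 0.25))
  # coupled: activity a deterministic function of trajectory + small noise
  act <- cbind(traj, traj) + rnorm(n_tr * 128, 0, 0.4)
  pc3 <- pattern_correlation_curve(act, traj)
  occ3 <- which(pc3$curve$n > 2)
  expect_gt(cor(pc3$curve$bin_lo[occ3], pc3$curve$mean[occ3]), 0.8)
})

test_that("ensemble difference follows the printed formula", {
  expect_equal(ensemble_difference(3, 3), 0)
  expect_equal(ensemble_difference(3, 1), 1.0)
  expect_equal(ensemble_difference(0, 5), 2.0)
  expect_true(is.na(ensemble_difference(0, 0)))
  set.seed(21)
  a <- rpois(50, 5); b <- rpois(50, 5)
  d <- ensemble_difference(a, b)
  expect_true(all(d[!is.na(d)] >= 0 & d[!is.na(d)] <= 2))
  expect_equal(d, ensemble_difference(b, a))
  expect_equal(d, ensemble_difference(3 * a, 3 * b))
})

test_that("ensemble difference curve skips undefined pairs", {
  counts <- c(0, 0, 3, 1)
  traj <- matrix(rnorm(4 * 16), 4)
  ec <- ensemble_difference_curve(counts, traj)
  expect_equal(ec$n_skipped, 1)       # the (0, 0) pair
  expect_equal(nrow(ec$pairs), 5)
})

test_that("activated counts use the post-onset window", {
  ev <- list(b1 = ev_df(c(10.5, 30.0)), b2 = ev_df(14.0))
  counts <- activated_counts(ev, c("b1", "b2"), c(10, 28))
  expect_equal(counts, c(1L, 1L))
  expect_equal(activated_counts(ev, c("b1", "b2"), 13.5), 1L)
})

test_that("axon heterogeneity counts the minority label", {
  expect_equal(axon_heterogeneity(rep("RM_only", 6))$heterogeneity, 0)
  h <- axon_heterogeneity(c(rep("RM_only", 9), "UM_only"))
  expect_equal(h$heterogeneity, 0.1)
  tie <- axon_heterogeneity(c("RM_only", "RM_only", "UM_only", "UM_only"))
  expect_equal(tie$heterogeneity, 0.5)
  expect_true(tie$tie)
  # both-policy and unresponsive exclusion
  cats <- c("RM_only", "RM_only", "both", "UM_only", "unresponsive")
  expect_equal(axon_heterogeneity(cats)$heterogeneity, 0.25)
  expect_equal(axon_heterogeneity(cats, "exclude")$heterogeneity, 1 / 3)
  expect_true(is.na(axon_heterogeneity(rep("unresponsive",
                                           4))$heterogeneity))
  # homogenisation is idempotent
  dom <- axon_heterogeneity(cats)$dominant
  relab <- rep(paste0(dom, "_only"), length(cats))
  expect_equal(axon_heterogeneity(relab)$heterogeneity, 0)
})

test_that("axon pair correlations split at 0.7", {
  set.seed(22)
  shared_ev <- bump_trace(4000, seq(100, 3900, by = 150), rep(4, 26))
  m <- cbind(a1 = shared_ev + rnorm(4000, 0, 0.5),
             a2 = shared_ev + rnorm(4000, 0, 0.5),
             a3 = rnorm(4000))
  pc <- axon_pair_correlation(m)
  r12 <- pc$pairs$r[pc$pairs$axon_a == "a1" & pc$pairs$axon_b == "a2"]
  expect_gt(r12, 0.7)
  expect_true(all(pc$pairs$r[pc$pairs$axon_b == "a3"] < 0.7))
  expect_equal(axon_pair_correlation(cbind(m[, 1], m[, 1]))$pairs$r, 1.0)
})

test_that("selectivity separation grows with response amplitude", {
  set.seed(23)
  mk <- function(delta) {
    fs <- 15; n <- 2400
    onsets <- data.frame(onset_s = seq(15, 140, by = 11),
                         label = rep(c("RM", "UM"), length.out = 12))
    z <- matrix(rnorm(n * 6), n, 6)
    for (r in seq_len(nrow(onsets))) {
      f <- round(onsets$onset_s[r] * fs)
      cols <- if (onsets$label[r] == "RM") 1:3 else 4:6
      for (cc in cols) z[f:(f + 20), cc] <- z[f:(f + 20), cc] + delta
    }
    mean(trajectory_selectivity(pc_trajectories(z, onsets, fs))$index)
  }
  expect_gt(mk(3), mk(0.5))
})
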