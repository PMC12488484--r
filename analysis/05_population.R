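#!/usr/bin/env Rscript
# Population-level analyses: PCA embedding of trial-averaged bouton
# activity, per-trial PC trajectories and the RM/UM selectivity index,
# activity-pattern and ensemble-difference curves against movement
# similarity, axon heterogeneity and axon-pair correlations.

source(file.path("analysis", "00_config.R"))

ds <- load_dataset(DATA_DIR)
bouts <- read.delim(file.path(RESULTS, "bouts.tsv"))
labels <- read.delim(file.path(RESULTS, "labels.tsv"))
onsets <- with(bouts[bouts$label %in% c("RM", "UM"), ],
               data.frame(onset_s = onset_s, label = label))
fs <- ds$fs_hz

b_ids <- labels$unit_id
dff <- lapply(b_ids, function(id) compute_dff(ds$fluor[, id], fs))
names(dff) <- b_ids
z_mat <- do.call(cbind, lapply(dff, `[[`, "z"))

# PCA embedding of trial-averaged activity per bouton
rm_on <- onsets$onset_s[onsets$label == "RM"]
um_on <- onsets$onset_s[onsets$label == "UM"]
rm_means <- t(vapply(b_ids, function(id)
  align_to_onsets(dff[[id]]$z, rm_on, fs)$mean_trace, numeric(60)))
um_means <- t(vapply(b_ids, function(id)
  align_to_onsets(dff[[id]]$z, um_on, fs)$mean_trace, numeric(60)))
emb <- embed_boutons(rm_means, um_means)
write_tsv(data.frame(roi_id = b_ids, emb$scores), "embedding.tsv")
message(sprintf("embedding: %d x %d matrix, first 3 PCs carry %.0f%% variance",
                emb$matrix_dim[1], emb$matrix_dim[2],
                100 * sum(emb$sdev[1:3]^2) / sum(emb$sdev^2)))

# trajectory selectivity on the continuous segment
sel <- trajectory_selectivity(pc_trajectories(z_mat, onsets, fs))
write_tsv(sel, "selectivity.tsv")
sel_mean <- aggregate(index ~ label, sel, mean)
message(sprintf("mean selectivity index: RM %.2f, UM %.2f",
                sel_mean$index[sel_mean$label == "RM"],
                sel_mean$index[sel_mean$label == "UM"]))

# pattern-correlation and ensemble-difference curves vs movement
# trajectory correlation
resp_ids <- labels$unit_id[!is.na(labels$category) &
                             labels$category != "unresponsive"]
keep <- !is.na(bouts$trial_id) & bouts$label %in% c("RM", "UM")
mv <- bouts[keep, ]
traj <- bout_trajectories(mv, ds$lever)
full <- stats::complete.cases(traj)
mv <- mv[full, ]; traj <- traj[full, , drop = FALSE]
act <- t(vapply(seq_len(nrow(mv)), function(i) {
  unlist(lapply(resp_ids, function(id)
    align_to_onsets(dff[[id]]$z, mv$onset_s[i], fs)$mean_trace))
}, numeric(60 * length(resp_ids))))
pcur <- pattern_correlation_curve(act, traj)
write_tsv(cbind(statistic = "pattern_correlation", pcur$curve),
          "pattern_correlation_curve.tsv")

events <- lapply(dff, detect_events)
counts <- activated_counts(events, resp_ids, mv$onset_s)
ecur <- ensemble_difference_curve(counts, traj)
write_tsv(cbind(statistic = "ensemble_difference", ecur$curve),
          "ensemble_difference_curve.tsv")
occ <- pcur$curve$n > 0
message(sprintf("pattern correlation rises %.2f -> %.2f across occupied bins",
                pcur$curve$mean[which(occ)[1]],
                pcur$curve$mean[rev(which(occ))[1]]))

# axon heterogeneity and axon-pair correlation
het <- vapply(split(labels$category, labels$axon_id), function(cc)
  axon_heterogeneity(cc[!is.na(cc)])$heterogeneity, numeric(1))
write_tsv(data.frame(axon_id = names(het), heterogeneity = het),
          "heterogeneity.tsv")
shafts <- grep("_shaft$", colnames(ds$fluor), value = TRUE)
axon_z <- vapply(shafts, function(id) compute_dff(ds$fluor[, id], fs)$z,
                 numeric(nrow(ds$fluor)))
apc <- axon_pair_correlation(axon_z)
write_tsv(apc$pairs, "axon_pair_correlation.tsv")
message(sprintf("mean heterogeneity %.3f; %.0f%% of axon pairs with r > 0.7",
                mean(het, na.rm = TRUE), 100 * apc$frac_high))
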