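#!/usr/bin/env Rscript
# Segment the lever trace into movement bouts, label rewarded (RM) vs
# unrewarded (UM) movements, and summarise session behaviour.

source(file.path("analysis", "00_config.R"))

ds <- load_dataset(DATA_DIR)
bouts <- detect_movement_bouts(ds$lever, threshold_mm = 0.3)
bouts <- label_movements(bouts, ds$trials, push_threshold_mm = 1.5)
metrics <- session_metrics(ds$trials, bouts, ds$lever)

write_tsv(bouts, "bouts.tsv")
write_tsv(data.frame(metric = names(unlist(metrics)),
                     value = unlist(metrics)), "session_metrics.tsv")

message(sprintf("bouts: %d RM, %d UM, %d excluded",
                sum(bouts$label == "RM"), sum(bouts$label == "UM"),
                sum(bouts$label == "excluded")))
message(sprintf("success rate %.2f, mean reaction time %.2f s, %.1f ITI pushes/min",
                metrics$success_rate, metrics$mean_reaction_time_s,
                metrics$iti_push_rate_per_min))

# trajectory consistency: distribution of pairwise trajectory correlations
tr <- bout_trajectories(bouts[bouts$label == "RM", ], ds$lever)
tr <- tr[stats::complete.cases(tr), , drop = FALSE]
if (nrow(tr) >= 2) {
  pr <- utils::combn(nrow(tr), 2)
  rr <- vapply(seq_len(ncol(pr)), function(k)
    trajectory_correlation(tr[pr[1, k], ], tr[pr[2, k], ]), numeric(1))
  message(sprintf("RM trajectory correlation: median %.2f over %d pairs",
                  stats::median(rr, na.rm = TRUE), length(rr)))
}
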