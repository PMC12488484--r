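#!/usr/bin/env Rscript
# Generate the synthetic session analysed by the rest of the workflow:
# cued lever-pushing behaviour, bouton/shaft fluorescence with per-event
# ground truth, and a 4-session structural map series with clustered
# bouton formation. Writes the dataset as TSV tables plus truth.json.

source(file.path("analysis", "00_config.R"))

cfg <- workflow_config()
sim <- simulate_dataset(cfg)
unlink(DATA_DIR, recursive = TRUE)
write_dataset(sim, DATA_DIR)

truth <- sim$activity$truth$boutons
message(sprintf("dataset: %d trials, %d pushes (%d RM / %d UM)",
                nrow(sim$behavior$trials), nrow(sim$behavior$pushes),
                sum(sim$behavior$pushes$label == "RM"),
                sum(sim$behavior$pushes$label == "UM")))
message(sprintf("activity: %d ROIs x %d frames; true categories: %s",
                ncol(sim$activity$fluor), nrow(sim$activity$fluor),
                paste(names(table(truth$category)), table(truth$category),
                      sep = "=", collapse = ", ")))
message(sprintf("structure: %d sessions, %d bouton-session records",
                length(unique(sim$structure$maps$session)),
                nrow(sim$structure$maps)))
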