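#!/usr/bin/env Rscript
# Align each bouton's z trace to RM and UM onsets, classify
# responsiveness with the peak-minus-5th-percentile criterion (0.9 z
# units), and compare the resulting categories with the generator's
# ground truth.

source(file.path("analysis", "00_config.R"))

ds <- load_dataset(DATA_DIR)
rep <- run_pipeline(ds, pipeline_config(
  stages = c("behavior", "signals", "responsiveness")))
labels <- rep$responsiveness$labels
write_tsv(labels, "labels.tsv")

truth <- jsonlite::read_json(file.path(DATA_DIR, "truth.json"),
                             simplifyVector = TRUE)$boutons
est <- labels$category[match(truth$roi_id, labels$unit_id)]
acc <- mean(est == truth$category, na.rm = TRUE)
message(sprintf("categories: %s",
                paste(names(table(labels$category)),
                      table(labels$category), sep = "=", collapse = ", ")))
message(sprintf("agreement with ground truth: %.1f%% (%d unclassified)",
                100 * acc, sum(is.na(est))))

fate <- track_fate(data.frame(unit_id = truth$roi_id,
                              category = truth$category),
                   data.frame(unit_id = truth$roi_id, category = est))
write_tsv(as.data.frame(fate$counts), "truth_vs_estimated_counts.tsv")
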