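# Shared settings for the analysis workflow. Every driver sources this
# file, generates or loads data under results/, and writes its tables
# there. Sizes are kept modest so the whole workflow runs in about a
# minute on a laptop; the package's tests exercise the same code at the
# scales used for validation.

library(boutondyn)

RESULTS <- file.path("results")
# the simulated dataset is bulky and fully regenerable: keep it out of the
# curated results tables
DATA_DIR <- file.path("scratch", "dataset")
dir.create(RESULTS, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

workflow_config <- function(seed = 20260921) {
  sim_config(
    n_axons = 12, boutons_per_axon = 5,
    segment_s = 700, n_trials = 45, p_rm = 0.55, p_push_fail = 1,
    iti_push_rate_hz = 0.02,
    shared_event_fraction = 0.7,
    turnover = list(p_form = 0.45, p_elim = 0.15, cluster_sigma_um = 10,
                    axon_length_um = 100, n_sessions = 4),
    seed = seed)
}

write_tsv <- function(x, name) {
  write.table(x, file.path(RESULTS, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
  message("wrote results/", name)
}
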