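#!/usr/bin/env Rscript
# Structural bouton dynamics: formation/elimination/density between
# adjacent sessions, survival of the session-2 formed cohort, and the
# nearest-neighbour-distance clustering test on newly formed boutons.

source(file.path("analysis", "00_config.R"))

ds <- load_dataset(DATA_DIR)
truth <- jsonlite::read_json(file.path(DATA_DIR, "truth.json"),
                             simplifyVector = TRUE)
L <- truth$axon_length_um
sessions <- sort(unique(ds$maps$session))

turn <- do.call(rbind, lapply(seq_len(length(sessions) - 1), function(k) {
  tr <- compute_turnover(ds$maps, sessions[k], sessions[k + 1], L)
  cbind(pair = paste(sessions[k], sessions[k + 1], sep = "->"),
        tr$per_axon)
}))
write_tsv(turn, "turnover.tsv")
tot <- aggregate(cbind(n_formed, n_eliminated, n_prev) ~ pair, turn, sum)
message(paste(sprintf("%s: formation %.2f, elimination %.2f",
                      tot$pair, tot$n_formed / tot$n_prev,
                      tot$n_eliminated / tot$n_prev), collapse = "; "))

surv <- survival_curve(ds$maps, sessions[2])
write_tsv(surv, "survival.tsv")
message(sprintf("survival of the session-%d cohort: %s", sessions[2],
                paste(sprintf("%.2f", surv$survival), collapse = " ")))

# NND test on newly formed boutons (the generator clusters them at
# sigma = 10 um around per-axon centres)
s1 <- ds$maps[ds$maps$session == sessions[1], ]
s2 <- ds$maps[ds$maps$session == sessions[2], ]
pos <- lapply(split(s2, s2$axon_id), function(df)
  df$position_um[!df$bouton_id %in% s1$bouton_id])
nnd <- nnd_analysis(pos, L, n_shuffles = 1000, seed = 77)
write_tsv(data.frame(grid_um = nnd$grid_um, obs_cdf = nnd$obs_cdf,
                     band_lo = nnd$band_lo, band_hi = nnd$band_hi,
                     shuffle_mean = nnd$shuffle_mean), "nnd.tsv")
message(sprintf(
  "NND clustering: %s (max excursion %.3f vs critical %.3f); exceedance %s um",
  if (nnd$significant) "significant" else "not significant",
  nnd$d_obs, nnd$d_crit,
  paste(round(nnd$exceedance_range_um, 1), collapse = "-")))
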