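#!/usr/bin/env Rscript
# Extract dF/F with the 30-s 30th-percentile sliding baseline, detect
# calcium events (strict local maxima of the z-scored trace above 1
# s.d.), and partition bouton events into same vs unique peaks with the
# 670-ms matcher.

source(file.path("analysis", "00_config.R"))

ds <- load_dataset(DATA_DIR)
bouts <- read.delim(file.path(RESULTS, "bouts.tsv"))
onsets <- with(bouts[bouts$label %in% c("RM", "UM"), ],
               data.frame(onset_s = onset_s, label = label))

dff <- lapply(colnames(ds$fluor), function(id)
  compute_dff(ds$fluor[, id], ds$fs_hz))
names(dff) <- colnames(ds$fluor)
events <- lapply(dff, detect_events)

ev_tab <- do.call(rbind, lapply(names(events), function(id) {
  ev <- events[[id]]
  if (!nrow(ev)) return(NULL)
  ev$movement <- label_events_by_movement(ev, onsets)
  cbind(roi_id = id, ev)
}))
write_tsv(ev_tab, "events.tsv")

spf <- same_peak_fraction(events, ds$rois)
write_tsv(spf$per_axon, "same_peak_by_axon.tsv")
message(sprintf("events: %d across %d ROIs; per-mouse same-peak fraction %.3f",
                nrow(ev_tab), length(events), spf$mouse_mean))

# bouton-shaft coupling, full-segment mode
b_rois <- ds$rois[ds$rois$kind == "bouton", ]
bs <- vapply(seq_len(nrow(b_rois)), function(i) {
  shaft <- paste0(b_rois$axon_id[i], "_shaft")
  shaft_bouton_correlation(dff[[b_rois$roi_id[i]]], dff[[shaft]])
}, numeric(1))
write_tsv(data.frame(roi_id = b_rois$roi_id, axon_id = b_rois$axon_id,
                     shaft_r = bs), "bouton_shaft_correlation.tsv")
message(sprintf("bouton-shaft correlation: median %.2f", median(bs)))
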