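#' Simulate a complete dataset (behaviour, activity, structure)
#'
#' Convenience wrapper running [simulate_behavior()],
#' [simulate_activity()] and [simulate_bouton_maps()] from one
#' configuration. Each generator uses its own named substream of the
#' master seed, so the parts can be regenerated independently.
#'
#' @param config a [sim_config()]
#' @return list of class `bouton_sim`: `behavior`, `activity`, `structure`,
#'   `config`
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  out <- list(behavior = simulate_behavior(config),
              activity = simulate_activity(
                simulate_behavior(config), config),
              structure = simulate_bouton_maps(config),
              config = config)
  class(out) <- "bouton_sim"
  out
}

#' Write a simulated dataset to a directory of TSV tables
#'
#' Emits `lever.tsv`, `trials.tsv`, `fluor.tsv` (frames x ROIs),
#' `rois.tsv`, `maps.tsv` and `truth.json`, the on-disk schema read back
#' by [load_dataset()].
#'
#' @param sim a `bouton_sim` from [simulate_dataset()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "bouton_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f)
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(sim$behavior$lever, "lever.tsv")
  tsv(sim$behavior$trials, "trials.tsv")
  tsv(as.data.frame(sim$activity$fluor), "fluor.tsv")
  tsv(sim$activity$rois, "rois.tsv")
  tsv(sim$structure$maps, "maps.tsv")
  truth <- list(fs_hz = sim$activity$fs_hz,
                push_threshold_mm = sim$behavior$push_threshold_mm,
                pushes = sim$behavior$pushes,
                boutons = sim$activity$truth$boutons,
                events = sim$activity$truth$events,
                structure = sim$structure$truth,
                axon_length_um = sim$structure$axon_length_um)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load and validate a dataset directory
#'
#' Reads the TSV tables written by [write_dataset()] (or prepared in the
#' same schema), checks that time is strictly increasing and uniformly
#' sampled, that every fluorescence column resolves to an ROI, that every
#' bouton ROI carries an axon id, and that rewards never precede cues.
#' Violations are reported with the offending id or row.
#'
#' @param dir dataset directory
#' @return list of class `bouton_dataset`: `lever`, `trials`, `fluor`
#'   (matrix), `rois`, `maps` (or `NULL`), `fs_hz`
#' @export
load_dataset <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing required table: ", f)
    read.delim(p, stringsAsFactors = FALSE)
  }
  lever <- need("lever.tsv")
  trials <- need("trials.tsv")
  fluor_df <- need("fluor.tsv")
  rois <- need("rois.tsv")
  maps <- if (file.exists(file.path(dir, "maps.tsv")))
    read.delim(file.path(dir, "maps.tsv"), stringsAsFactors = FALSE)
  else NULL

  validate_lever(lever)
  for (col in c("roi_id", "kind", "axon_id"))
    if (!col %in% names(rois)) stop("rois.tsv missing column: ", col)
  bad <- rois$roi_id[rois$kind == "bouton" &
                       (is.na(rois$axon_id) | rois$axon_id == "")]
  if (length(bad))
    stop("bouton ROI(s) without axon_id: ", paste(head(bad, 5),
                                                  collapse = ", "))
  dangling <- setdiff(names(fluor_df), rois$roi_id)
  if (length(dangling))
    stop("fluor.tsv column(s) absent from rois.tsv: ",
         paste(head(dangling, 5), collapse = ", "))
  if ("reward_time_s" %in% names(trials)) {
    bad_tr <- trials$trial_id[!is.na(trials$reward_time_s) &
                                trials$reward_time_s < trials$cue_time_s]
    if (length(bad_tr))
      stop("reward precedes cue in trial(s): ",
           paste(bad_tr, collapse = ", "))
  }
  fs <- 1 / stats::median(diff(lever$time_s))
  out <- list(lever = lever, trials = trials,
              fluor = as.matrix(fluor_df), rois = rois, maps = maps,
              fs_hz = fs)
  class(out) <- "bouton_dataset"
  out
}

#' Pipeline configuration
#'
#' Every tunable of the end-to-end pipeline with its default: detection
#' and matching thresholds, alignment windows, classification criteria,
#' binning, and the seed driving the structural shuffles.
#'
#' @param ... overrides of the defaults; unknown keys are rejected
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(movement_threshold_mm = NULL, push_threshold_mm = 1.5,
              merge_gap_s = 0.5, exclusion_window_s = 3,
              dff_window_s = 30, dff_percentile = 30,
              baseline_align = "centered", event_threshold_sd = 1,
              match_tol_s = 0.67, event_label_pre_s = 0.33,
              event_label_post_s = 0.67, align_pre_s = 1, align_post_s = 3,
              peak_window = c(-0.2, 3), criterion_sd = 0.9,
              axon_bin_sd = 0.1, axon_cap_sd = 1, min_trials = 5,
              heterogeneity_both_policy = "dominant",
              activation_window_s = 3, traj_pre_s = 0.5, traj_post_s = 2,
              traj_points = 64, nnd_shuffles = 1000, nnd_match = "id",
              seed = 1,
              stages = c("behavior", "signals", "responsiveness",
                         "population", "structure"))
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown,
                                                   collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes behaviour segmentation, dF/F extraction and event detection,
#' same/unique-peak matching, responsiveness classification, population
#' summaries (heterogeneity, trajectory selectivity) and, when maps are
#' present, structural turnover. Deterministic given `config$seed` (the
#' only randomised stage is the structural shuffle null). When `out_dir`
#' is given the per-stage tables are written there; the directory must not
#' already contain a run (outputs are write-once).
#'
#' @param dataset a `bouton_dataset` (from [load_dataset()]) or a
#'   `bouton_sim` (used directly, without a disk round trip)
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory
#' @return list of class `pipeline_report` with per-stage results and the
#'   resolved configuration
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         out_dir = NULL) {
  if (inherits(dataset, "bouton_sim")) {
    ds <- list(lever = dataset$behavior$lever,
               trials = dataset$behavior$trials,
               fluor = dataset$activity$fluor,
               rois = dataset$activity$rois,
               maps = dataset$structure$maps,
               fs_hz = dataset$activity$fs_hz,
               axon_length_um = dataset$structure$axon_length_um)
  } else {
    stopifnot(inherits(dataset, "bouton_dataset"))
    ds <- dataset
  }
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)))
      stop("out_dir already contains a run (outputs are write-once): ",
           out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  report <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # ---- behaviour ----
  bouts <- NULL; onsets <- NULL
  if ("behavior" %in% config$stages) {
    report$behavior <- stage("behavior", {
      bouts <- detect_movement_bouts(ds$lever,
                                     config$movement_threshold_mm,
                                     config$merge_gap_s,
                                     config$exclusion_window_s)
      bouts <- label_movements(bouts, ds$trials,
                               config$push_threshold_mm)
      metrics <- session_metrics(ds$trials, bouts, ds$lever,
                                 config$push_threshold_mm)
      list(bouts = bouts, metrics = metrics)
    })
    bouts <- report$behavior$bouts
    keep <- bouts$label %in% c("RM", "UM")
    onsets <- data.frame(onset_s = bouts$onset_s[keep],
                         label = bouts$label[keep],
                         stringsAsFactors = FALSE)
  }

  # ---- signals ----
  dff_list <- NULL; events_by_roi <- NULL
  if ("signals" %in% config$stages) {
    report$signals <- stage("signals", {
      dff_list <- lapply(seq_len(ncol(ds$fluor)), function(j)
        compute_dff(ds$fluor[, j], ds$fs_hz, config$dff_window_s,
                    config$dff_percentile,
                    align = config$baseline_align))
      names(dff_list) <- colnames(ds$fluor)
      events_by_roi <- lapply(dff_list, detect_events,
                              threshold_sd = config$event_threshold_sd)
      spf <- same_peak_fraction(events_by_roi, ds$rois, scope = "all",
                                tol_s = config$match_tol_s)
      list(events_by_roi = events_by_roi, same_peak = spf)
    })
    events_by_roi <- report$signals$events_by_roi
  }

  # ---- responsiveness ----
  labels <- NULL
  if ("responsiveness" %in% config$stages && !is.null(onsets) &&
        !is.null(dff_list)) {
    report$responsiveness <- stage("responsiveness", {
      b_rois <- ds$rois[ds$rois$kind == "bouton", , drop = FALSE]
      rm_on <- onsets$onset_s[onsets$label == "RM"]
      um_on <- onsets$onset_s[onsets$label == "UM"]
      classify_one <- function(id, on) {
        if (length(on) < config$min_trials) return(NA)
        al <- align_to_onsets(dff_list[[id]]$z, on, ds$fs_hz,
                              config$align_pre_s, config$align_post_s)
        if (nrow(al$mat) < config$min_trials) return(NA)
        classify_bouton_responsive(al, config$peak_window,
                                   config$criterion_sd)
      }
      resp_rm <- vapply(b_rois$roi_id, classify_one, logical(1),
                        on = rm_on)
      resp_um <- vapply(b_rois$roi_id, classify_one, logical(1),
                        on = um_on)
      labels <- data.frame(unit_id = b_rois$roi_id,
                           axon_id = b_rois$axon_id, level = "bouton",
                           resp_rm = resp_rm, resp_um = resp_um,
                           category = categorize_response(resp_rm,
                                                          resp_um),
                           stringsAsFactors = FALSE)
      list(labels = labels,
           n_unclassified = sum(is.na(labels$category)))
    })
    labels <- report$responsiveness$labels
  }

  # ---- population ----
  if ("population" %in% config$stages && !is.null(labels)) {
    report$population <- stage("population", {
      het <- lapply(split(labels$category, labels$axon_id), function(cc) {
        cc <- cc[!is.na(cc)]
        if (sum(cc != "unresponsive") < 2) return(NULL)
        axon_heterogeneity(cc, config$heterogeneity_both_policy)
      })
      het <- het[!vapply(het, is.null, logical(1))]
      het_df <- data.frame(axon_id = names(het),
                           heterogeneity = vapply(het, `[[`, numeric(1),
                                                  "heterogeneity"),
                           stringsAsFactors = FALSE)
      b_ids <- labels$unit_id
      z_mat <- do.call(cbind, lapply(dff_list[b_ids], `[[`, "z"))
      sel_mean <- NULL
      if (length(b_ids) >= 3 &&
            sum(onsets$label == "RM") >= 1 &&
            sum(onsets$label == "UM") >= 1) {
        trajs <- pc_trajectories(z_mat, onsets, ds$fs_hz,
                                 config$align_pre_s, config$align_post_s)
        sel <- trajectory_selectivity(trajs)
        if (!is.null(sel))
          sel_mean <- aggregate(index ~ label, sel, mean)
      }
      list(heterogeneity = het_df,
           mean_heterogeneity = if (nrow(het_df))
             mean(het_df$heterogeneity, na.rm = TRUE) else NA_real_,
           selectivity_by_label = sel_mean)
    })
  }

  # ---- structure ----
  if ("structure" %in% config$stages && !is.null(ds$maps) &&
        nrow(ds$maps)) {
    report$structure <- stage("structure", {
      sessions <- sort(unique(ds$maps$session))
      axon_len <- if (!is.null(ds$axon_length_um)) ds$axon_length_um
        else max(ds$maps$position_um)
      turn <- lapply(seq_len(length(sessions) - 1), function(k)
        compute_turnover(ds$maps, sessions[k], sessions[k + 1],
                         axon_len, match = config$nnd_match))
      names(turn) <- paste(sessions[-length(sessions)],
                           sessions[-1], sep = "->")
      surv <- if (length(sessions) >= 3)
        survival_curve(ds$maps, sessions[2]) else NULL
      list(turnover = turn, survival = surv)
    })
  }

  if (!is.null(out_dir)) write_report(report, out_dir)
  class(report) <- "pipeline_report"
  report
}

write_report <- function(report, out_dir) {
  tsv <- function(x, f)
    write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(report$behavior)) tsv(report$behavior$bouts, "bouts.tsv")
  if (!is.null(report$responsiveness))
    tsv(report$responsiveness$labels, "labels.tsv")
  if (!is.null(report$signals))
    tsv(report$signals$same_peak$per_axon, "same_peak.tsv")
  if (!is.null(report$population))
    tsv(report$population$heterogeneity, "heterogeneity.tsv")
  if (!is.null(report$structure)) {
    turn <- do.call(rbind, lapply(names(report$structure$turnover),
                                  function(nm) {
      cbind(pair = nm, report$structure$turnover[[nm]]$per_axon)
    }))
    tsv(turn, "turnover.tsv")
  }
  summary <- list(
    metrics = report$behavior$metrics,
    same_peak_mouse_mean = report$signals$same_peak$mouse_mean,
    mean_heterogeneity = report$population$mean_heterogeneity)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
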