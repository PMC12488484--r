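#' Simulate multi-session structural bouton maps
#'
#' Places boutons uniformly along each axon in session 1, then applies
#' per-session elimination (each bouton lost with probability `p_elim`)
#' and formation (a Binomial(previous count, `p_form`) number of new
#' boutons). Formed boutons are positioned uniformly along the axon, or —
#' when `cluster_sigma_um` is set — around a per-axon cluster centre with
#' Gaussian s.d. `cluster_sigma_um` (reflected into the axon), emulating
#' spatially clustered bouton formation. Bouton ids are persistent across
#' sessions.
#'
#' @param config a [sim_config()]; the `turnover` entry supplies `p_form`,
#'   `p_elim`, `cluster_sigma_um`, `axon_length_um` and `n_sessions`
#' @return a list of class `bouton_map_series`: `maps` (`session`,
#'   `axon_id`, `bouton_id`, `position_um`), `axon_length_um`, and `truth`
#'   with per-session-pair `formed`/`eliminated` id sets and
#'   `cluster_centres`
#' @export
simulate_bouton_maps <- function(config) {
  config <- validate_sim_config(config)
  set.seed(substream_seed(config$seed, "structure"))
  tv <- config$turnover
  L <- tv$axon_length_um
  clustered <- !is.null(tv$cluster_sigma_um)

  reflect <- function(x) {
    # fold positions back into [0, L]
    x <- abs(x)
    x <- ifelse(x > L, 2 * L - x, x)
    pmin(pmax(x, 0), L)
  }

  maps <- list(); truth <- list(); centres <- numeric(config$n_axons)
  counter <- 0L
  for (ax in seq_len(config$n_axons)) {
    axon_id <- sprintf("a%03d", ax)
    centres[ax] <- runif(1, 0.2 * L, 0.8 * L)
    ids <- sprintf("b%05d", counter + seq_len(config$boutons_per_axon))
    counter <- counter + config$boutons_per_axon
    pos <- runif(config$boutons_per_axon, 0, L)
    cur <- data.frame(bouton_id = ids, position_um = pos,
                      stringsAsFactors = FALSE)
    maps[[length(maps) + 1L]] <-
      cbind(session = 1L, axon_id = axon_id, cur)
    for (ss in 2:tv$n_sessions) {
      lost <- runif(nrow(cur)) < tv$p_elim
      eliminated <- cur$bouton_id[lost]
      n_new <- rbinom(1, nrow(cur), tv$p_form)
      cur <- cur[!lost, , drop = FALSE]
      formed <- character(0)
      if (n_new > 0) {
        new_pos <- if (clustered)
          reflect(rnorm(n_new, centres[ax], tv$cluster_sigma_um))
        else runif(n_new, 0, L)
        formed <- sprintf("b%05d", counter + seq_len(n_new))
        counter <- counter + n_new
        cur <- rbind(cur, data.frame(bouton_id = formed,
                                     position_um = new_pos,
                                     stringsAsFactors = FALSE))
      }
      if (nrow(cur))
        maps[[length(maps) + 1L]] <-
          cbind(session = ss, axon_id = axon_id, cur)
      key <- sprintf("%s_s%d", axon_id, ss)
      truth[[key]] <- list(axon_id = axon_id, session = ss,
                           formed = formed, eliminated = eliminated)
    }
  }
  maps <- do.call(rbind, maps)
  rownames(maps) <- NULL
  out <- list(maps = maps, axon_length_um = L,
              truth = list(changes = truth,
                           cluster_centres = if (clustered)
                             data.frame(axon_id = sprintf("a%03d",
                                          seq_len(config$n_axons)),
                                        centre_um = centres)
                           else NULL))
  class(out) <- "bouton_map_series"
  out
}
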