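#' Bouton turnover between two imaging sessions
#'
#' Compares the bouton maps of two adjacent sessions per axon. Boutons
#' present in both sessions are persistent; boutons present only in the
#' earlier (later) session are eliminated (formed). Matching uses
#' persistent bouton ids (`match = "id"`, synthetic maps) or greedy
#' nearest-position matching within `tol_um` (`match = "position"`, maps
#' without persistent ids). Formation and elimination rates share the
#' previous-session count as denominator, so they are directly comparable;
#' density is the current count per micrometre of traced axon.
#'
#' @param maps bouton map table: `session`, `axon_id`, `bouton_id`,
#'   `position_um`
#' @param s_prev,s_curr the two session ids to compare
#' @param axon_length_um axon length (scalar, or named vector by axon id)
#' @param match `"id"` or `"position"`
#' @param tol_um position-matching tolerance (default 2)
#' @return list of class `turnover_record`: `per_axon` (counts, rates,
#'   density per axon), `total` (pooled counts and rates),
#'   `excluded_axons` (present in only one session)
#' @export
compute_turnover <- function(maps, s_prev, s_curr, axon_length_um,
                             match = c("id", "position"), tol_um = 2) {
  match <- match.arg(match)
  prev <- maps[maps$session == s_prev, , drop = FALSE]
  curr <- maps[maps$session == s_curr, , drop = FALSE]
  # an entirely empty session means total elimination (or formation), not
  # missing axons; axons absent from one non-empty session are excluded
  if (nrow(curr) == 0 || nrow(prev) == 0) {
    axons <- unique(c(prev$axon_id, curr$axon_id))
    excluded <- character(0)
  } else {
    axons <- intersect(unique(prev$axon_id), unique(curr$axon_id))
    excluded <- setdiff(union(unique(prev$axon_id), unique(curr$axon_id)),
                        axons)
  }
  len_of <- function(ax) {
    if (length(axon_length_um) == 1L && is.null(names(axon_length_um)))
      axon_length_um else unname(axon_length_um[ax])
  }
  rows <- lapply(axons, function(ax) {
    p <- prev[prev$axon_id == ax, , drop = FALSE]
    q <- curr[curr$axon_id == ax, , drop = FALSE]
    if (match == "id") {
      n_pers <- length(intersect(p$bouton_id, q$bouton_id))
    } else {
      n_pers <- match_positions(p$position_um, q$position_um, tol_um)
    }
    n_elim <- nrow(p) - n_pers
    n_form <- nrow(q) - n_pers
    data.frame(axon_id = ax, n_prev = nrow(p), n_curr = nrow(q),
               n_persistent = n_pers, n_formed = n_form,
               n_eliminated = n_elim,
               formation_rate = if (nrow(p)) n_form / nrow(p) else
                 NA_real_,
               elimination_rate = if (nrow(p)) n_elim / nrow(p) else
                 NA_real_,
               density = nrow(q) / len_of(ax), stringsAsFactors = FALSE)
  })
  per_axon <- do.call(rbind, rows)
  tot_prev <- sum(per_axon$n_prev)
  out <- list(per_axon = per_axon,
              total = list(
                n_persistent = sum(per_axon$n_persistent),
                n_formed = sum(per_axon$n_formed),
                n_eliminated = sum(per_axon$n_eliminated),
                formation_rate = if (tot_prev)
                  sum(per_axon$n_formed) / tot_prev else NA_real_,
                elimination_rate = if (tot_prev)
                  sum(per_axon$n_eliminated) / tot_prev else NA_real_),
              excluded_axons = excluded)
  class(out) <- "turnover_record"
  out
}

# greedy nearest-position matching within tolerance; returns the number of
# matched (persistent) boutons
match_positions <- function(p, q, tol_um) {
  if (!length(p) || !length(q)) return(0L)
  d <- abs(outer(p, q, "-"))
  n <- 0L
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = TRUE]
    if (d[m[1], m[2]] > tol_um) break
    n <- n + 1L
    d[m[1], ] <- Inf; d[, m[2]] <- Inf
    if (all(is.infinite(d))) break
  }
  n
}

#' Survival of a formed bouton cohort
#'
#' The cohort is every bouton present at `cohort_session` but absent at
#' the session before it (i.e. formed then). The curve gives the fraction
#' of the cohort still present at each later session; it is non-increasing
#' because a bouton that has disappeared is not re-counted even if an id
#' reappears.
#'
#' @param maps bouton map table (`session`, `axon_id`, `bouton_id`,
#'   `position_um`)
#' @param cohort_session session at which the cohort was first seen
#' @param sessions later sessions to evaluate (default: all sessions after
#'   `cohort_session`)
#' @return data frame `session`, `n_present`, `survival`; flagged empty
#'   (zero rows, attribute `empty_cohort`) when no bouton was formed
#' @export
survival_curve <- function(maps, cohort_session, sessions = NULL) {
  all_s <- sort(unique(maps$session))
  if (is.null(sessions)) sessions <- all_s[all_s > cohort_session]
  before <- all_s[all_s < cohort_session]
  ids_at <- function(s) maps$bouton_id[maps$session == s]
  cohort <- if (length(before))
    setdiff(ids_at(cohort_session), ids_at(max(before)))
  else ids_at(cohort_session)
  if (!length(cohort)) {
    out <- data.frame(session = integer(), n_present = integer(),
                      survival = numeric())
    attr(out, "empty_cohort") <- TRUE
    return(out)
  }
  alive <- cohort
  rows <- lapply(sort(sessions), function(s) {
    alive <<- intersect(alive, ids_at(s))
    data.frame(session = s, n_present = length(alive),
               survival = length(alive) / length(cohort))
  })
  out <- do.call(rbind, rows)
  attr(out, "cohort_size") <- length(cohort)
  out
}

#' Nearest-neighbour-distance clustering test with a permutation null
#'
#' For each axon with at least two boutons of interest, every bouton's
#' nearest-neighbour distance (NND) along the axon is computed and pooled
#' across axons. The null repositions the same number of boutons uniformly
#' along each axon `n_shuffles` times (`shuffle = "uniform"`), or permutes
#' the observed positions across axons (`shuffle = "permute"`), and
#' rebuilds the pooled NND CDF each time. The observed empirical CDF is
#' compared with the pointwise 2.5/97.5 percentile band of the shuffle
#' CDFs on a 1-um grid; the range of distances where the observed CDF
#' exceeds the upper band is the clustering exceedance range.
#'
#' @param positions_by_axon named list: bouton positions (um) per axon
#' @param axon_length_um axon length (scalar or named vector by axon)
#' @param n_shuffles number of position shuffles (default 1000; fewer than
#'   100 triggers a warning)
#' @param grid_step_um CDF evaluation grid step (default 1)
#' @param seed mandatory RNG seed for the shuffles
#' @param shuffle `"uniform"` (default) or `"permute"`
#' @return list of class `nnd_result`: `observed_nnd`, `grid_um`,
#'   `obs_cdf`, `band_lo`, `band_hi`, `shuffle_mean`, `exceed_above`
#'   (logical per grid point), `exceedance_range_um` (`c(NA, NA)` when
#'   none), `significant` (max-statistic clustering decision, calibrated
#'   on the shuffle distribution of the largest excursion above the
#'   pointwise band), `d_obs`, `d_crit`, `n_axons_used`, `n_skipped`
#' @export
nnd_analysis <- function(positions_by_axon, axon_length_um,
                         n_shuffles = 1000, grid_step_um = 1, seed,
                         shuffle = c("uniform", "permute")) {
  shuffle <- match.arg(shuffle)
  if (missing(seed)) stop("seed is required for reproducible shuffles")
  if (n_shuffles < 100)
    warning("n_shuffles < 100 gives an unreliable confidence band")
  set.seed(seed)

  keep <- vapply(positions_by_axon, length, integer(1)) >= 2
  n_skipped <- sum(!keep)
  pos <- positions_by_axon[keep]
  if (!length(pos)) stop("no axon has >= 2 boutons of interest")
  len_of <- function(ax) {
    if (length(axon_length_um) == 1L && is.null(names(axon_length_um)))
      axon_length_um else unname(axon_length_um[ax])
  }
  lens <- vapply(names(pos), len_of, numeric(1))

  obs <- unlist(lapply(pos, nnd_values), use.names = FALSE)
  grid <- seq(0, max(lens), by = grid_step_um)
  obs_cdf <- stats::ecdf(obs)(grid)

  ks <- vapply(pos, length, integer(1))
  n_tot <- sum(ks)
  # all shuffles at once: group rows by (shuffle, axon), sort positions
  # within groups via one order() call, take NNDs from within-group gaps
  shuf_id <- rep(seq_len(n_shuffles), each = n_tot)
  axon_id <- rep(rep.int(seq_along(pos), ks), times = n_shuffles)
  p <- if (shuffle == "uniform")
    runif(n_tot * n_shuffles, 0, rep(rep.int(lens, ks), n_shuffles))
  else
    as.numeric(vapply(seq_len(n_shuffles),
                      function(i) sample(unlist(pos, use.names = FALSE)),
                      numeric(n_tot)))
  o <- order(shuf_id, axon_id, p)
  ps <- p[o]
  grp <- paste0(shuf_id, "_", axon_id)[o]  # group key after ordering
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  gap <- c(Inf, diff(ps))
  gap[new_grp] <- Inf
  nnd <- pmin(gap, c(gap[-1], Inf))
  # per-shuffle CDF on the grid via binned counts + cumulative sums:
  # F_s(grid[j]) = #{nnd <= grid[j]} / n, with bidx = #{grid points < nnd}
  sid <- shuf_id[o]
  G <- length(grid)
  bidx <- findInterval(nnd, grid, left.open = TRUE)  # 0 .. G
  keep_b <- is.finite(nnd) & bidx <= G - 1L
  counts <- matrix(0L, n_shuffles, G)
  if (any(keep_b)) {
    tab <- tabulate((sid[keep_b] - 1L) * G + bidx[keep_b] + 1L,
                    n_shuffles * G)
    counts <- matrix(tab, n_shuffles, G, byrow = TRUE)
  }
  shuf_cdf <- t(apply(counts, 1, cumsum)) / n_tot
  band <- apply(shuf_cdf, 2, quantile, probs = c(0.025, 0.975), type = 7)
  exceed <- obs_cdf > band[2, ]
  rng <- if (any(exceed)) range(grid[exceed]) else c(NA_real_, NA_real_)
  # The pointwise band is descriptive; testing "exceeds anywhere" against
  # it is anti-conservative (many correlated grid points). The clustering
  # decision uses a max-statistic calibration from the same shuffles: the
  # null distribution of the largest excursion above the pointwise band.
  d_null <- apply(shuf_cdf - matrix(band[2, ], n_shuffles, length(grid),
                                    byrow = TRUE), 1, max)
  d_crit <- as.numeric(quantile(d_null, 0.95, type = 7))
  d_obs <- max(obs_cdf - band[2, ])
  out <- list(observed_nnd = obs, grid_um = grid, obs_cdf = obs_cdf,
              band_lo = band[1, ], band_hi = band[2, ],
              shuffle_mean = colMeans(shuf_cdf), exceed_above = exceed,
              exceedance_range_um = rng,
              significant = d_obs > d_crit, d_obs = d_obs,
              d_crit = d_crit, n_axons_used = length(pos),
              n_skipped = n_skipped)
  class(out) <- "nnd_result"
  out
}

#' Nearest-neighbour distances along one axon
#'
#' @param p bouton positions (um) on one axon (length >= 2)
#' @return one NND per bouton: the gap to its nearest neighbour
#' @export
nnd_values <- function(p) {
  stopifnot(length(p) >= 2)
  p <- sort(p)
  g <- diff(p)
  pmin(c(Inf, g), c(g, Inf))
}
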