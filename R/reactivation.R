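#' Peri-SWR population firing rate
#'
#' Spike counts in fixed-width time bins relative to each SWR centre,
#' averaged over events and divided by bin width; one curve per supplied
#' unit set (pass pyramidal cells and interneurons separately). A bootstrap
#' over events gives a confidence band.
#'
#' @param spike_times list of per-unit spike-time vectors
#' @param swr_events data frame with `t` (event centres), e.g. from
#'   [detect_swrs]
#' @param window_s half-window around the event centre (default 0.25)
#' @param bin_s bin width (default 0.01)
#' @param n_boot bootstrap replicates for the confidence band (default 200)
#' @param conf confidence level (default 0.95)
#' @return data frame: `t_rel` (bin centre), `rate_hz` (mean over events,
#'   averaged across units), `ci_lower`, `ci_upper`
#' @export
peri_swr_rates <- function(spike_times, swr_events, window_s = 0.25,
                           bin_s = 0.01, n_boot = 200, conf = 0.95) {
  ev <- swr_events$t
  if (length(ev) < 10) stop("need at least 10 SWR events")
  edges <- seq(-window_s, window_s, by = bin_s)
  n_bins <- length(edges) - 1L
  n_ev <- length(ev)
  # events x bins count matrix, pooled over units
  counts <- matrix(0, n_ev, n_bins)
  for (st in spike_times) {
    st <- sort(st)
    for (k in seq_len(n_ev)) {
      rel <- st[st >= ev[k] - window_s & st <= ev[k] + window_s] - ev[k]
      if (length(rel))
        counts[k, ] <- counts[k, ] + tabulate(findInterval(rel, edges,
                                                           rightmost.closed = TRUE),
                                              nbins = n_bins)
    }
  }
  per_unit <- length(spike_times)
  rate <- colMeans(counts) / bin_s / per_unit
  boot <- matrix(NA_real_, n_boot, n_bins)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_ev, n_ev, replace = TRUE)
    boot[b, ] <- colMeans(counts[idx, , drop = FALSE]) / bin_s / per_unit
  }
  a <- (1 - conf) / 2
  data.frame(t_rel = (edges[-1] + edges[-length(edges)]) / 2,
             rate_hz = rate,
             ci_lower = apply(boot, 2, stats::quantile, probs = a),
             ci_upper = apply(boot, 2, stats::quantile, probs = 1 - a))
}

#' Pairwise cofiring in 100-ms windows
#'
#' Instantaneous firing-rate counts in 100-ms windows laid over the given
#' intervals -- tiling them (waking theta periods) or, for SWR events, one
#' window centred on each event (`center_events = TRUE`; events shorter
#' than the window are padded to it). Pearson correlation of counts per
#' cell pair.
#'
#' @param spike_times list of per-unit spike-time vectors
#' @param intervals interval data frame (theta epochs, or SWR events with
#'   centres in `t`)
#' @param window_s window length (default 0.1)
#' @param center_events take one window per interval centred on its `t` (or
#'   midpoint) instead of tiling
#' @param min_spikes cells with fewer total in-window spikes have their
#'   pairs excluded (default 10)
#' @return `cofiring` data frame: `cell_i`, `cell_j`, `r`, `n_windows`
#' @export
cofiring <- function(spike_times, intervals, window_s = 0.1,
                     center_events = FALSE, min_spikes = 10) {
  if (nrow(intervals) == 0) stop("empty interval set")
  if (center_events) {
    centers <- if ("t" %in% names(intervals)) intervals$t
               else (intervals$start + intervals$end) / 2
    ws <- centers - window_s / 2
    we <- centers + window_s / 2
  } else {
    w <- iv_windows(intervals, window_s)
    ws <- w$start; we <- w$end
  }
  counts <- count_in_windows(spike_times, ws, we)
  tot <- colSums(counts)
  sds <- apply(counts, 2, stats::sd)
  n_cells <- length(spike_times)
  pairs <- utils::combn(n_cells, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- tot[i] >= min_spikes && tot[j] >= min_spikes &&
      sds[i] > 0 && sds[j] > 0
    data.frame(cell_i = i, cell_j = j,
               r = if (ok) stats::cor(counts[, i], counts[, j]) else NA_real_,
               n_windows = length(ws))
  })
  out <- do.call(rbind, out)
  attr(out, "variant") <- if (center_events) "swr_cofire" else "theta_cofire"
  class(out) <- c("cofiring", class(out))
  out
}

#' Reactivation strength: exploration-to-sleep cofiring similarity
#'
#' Pearson correlation, across cell pairs, between waking (theta-period)
#' cofiring and sleep (SWR-period) cofiring. High values mean pairs that
#' fired together during exploration also fire together in subsequent
#' sleep SWRs.
#'
#' @param waking_cofire,swr_cofire `cofiring` data frames over the same
#'   cells
#' @param min_pairs minimum common valid pairs (default 10)
#' @return list: `reactivation_r`, `n_pairs`
#' @export
reactivation_strength <- function(waking_cofire, swr_cofire, min_pairs = 10) {
  key1 <- paste(waking_cofire$cell_i, waking_cofire$cell_j)
  key2 <- paste(swr_cofire$cell_i, swr_cofire$cell_j)
  common <- intersect(key1, key2)
  r1 <- waking_cofire$r[match(common, key1)]
  r2 <- swr_cofire$r[match(common, key2)]
  ok <- !is.na(r1) & !is.na(r2)
  if (sum(ok) < min_pairs)
    stop("fewer than ", min_pairs, " common valid pairs")
  list(reactivation_r = stats::cor(r1[ok], r2[ok]), n_pairs = sum(ok))
}
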