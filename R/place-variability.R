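#' Index of dispersion of per-pass spike counts
#'
#' The place field is defined on the smoothed rate map at one or more
#' threshold levels (bins above `level * max`). For each level, passes are
#' the maximal contiguous runs of tracking samples inside the field region
#' (at least 2 consecutive in-field samples); the statistic is the
#' variance/mean ratio of the spike counts collected on each pass. Poisson
#' firing gives 1; location-independent rate modulation (e.g. assembly
#' gains) pushes it above 1.
#'
#' @param tracking data frame `t`, `x`, `y`
#' @param spike_times spike times of the unit (s)
#' @param map the unit's `rate_map`
#' @param levels field threshold levels as fractions of the map peak
#' @param min_passes passes required for a valid estimate (default 10)
#' @return data frame: `level`, `n_passes`, `mean_count`, `dispersion`
#'   (NA and flagged when passes are insufficient)
#' @export
index_of_dispersion <- function(tracking, spike_times, map,
                                levels = seq(0.1, 0.9, by = 0.1),
                                min_passes = 10) {
  nb <- nrow(map$smoothed_rate)
  peak <- max(map$smoothed_rate[map$visited])
  bin_of <- function(x) pmin(pmax(findInterval(x, map$bin_edges, rightmost.closed = TRUE), 1L), nb)
  ix <- bin_of(tracking$x); iy <- bin_of(tracking$y)
  lin <- cbind(ix, iy)
  st <- sort(spike_times)
  out <- lapply(levels, function(lv) {
    infield_bin <- map$smoothed_rate > lv * peak & map$visited
    inf <- infield_bin[lin]
    r <- rle(inf)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= 2
    if (!any(ok))
      return(data.frame(level = lv, n_passes = 0L, mean_count = NA_real_,
                        dispersion = NA_real_))
    s_idx <- starts[ok]; e_idx <- ends[ok]
    t_s <- tracking$t[s_idx]; t_e <- tracking$t[e_idx]
    counts <- findInterval(t_e, st) - findInterval(t_s, st, left.open = TRUE)
    n_p <- length(counts)
    disp <- if (n_p >= min_passes && mean(counts) > 0)
      stats::var(counts) / mean(counts) else NA_real_
    data.frame(level = lv, n_passes = n_p, mean_count = mean(counts),
               dispersion = disp)
  })
  do.call(rbind, out)
}

#' Speed modulation of firing rate
#'
#' Instantaneous firing-rate counts (IFRCs) in non-overlapping 500-ms
#' windows during exploration are z-scored per cell and correlated with the
#' mean running speed of the same windows.
#'
#' @param tracking data frame `t`, `x`, `y`
#' @param spike_times list of per-unit spike-time vectors
#' @param epoch optional interval data frame
#' @param window_s IFRC window (default 0.5 s)
#' @param min_windows minimum windows for a valid correlation (default 20)
#' @return data frame: `unit`, `r` (Pearson), `n_windows`; `r` is NA for
#'   zero-variance counts
#' @export
speed_rate_correlation <- function(tracking, spike_times, epoch = NULL,
                                   window_s = 0.5, min_windows = 20) {
  if (is.null(epoch))
    epoch <- iv_new(tracking$t[1], tracking$t[nrow(tracking)])
  w <- iv_windows(epoch, window_s)
  if (nrow(w) < min_windows) stop("fewer than ", min_windows, " windows")
  speed <- tracking_speed(tracking)
  # mean speed per window
  sp <- vapply(seq_len(nrow(w)), function(i) {
    idx <- tracking$t >= w$start[i] & tracking$t < w$end[i]
    mean(speed[idx])
  }, numeric(1))
  counts <- count_in_windows(spike_times, w$start, w$end)
  rs <- vapply(seq_along(spike_times), function(j) {
    cj <- counts[, j]
    if (stats::sd(cj) == 0 || stats::sd(sp, na.rm = TRUE) == 0) return(NA_real_)
    z <- (cj - mean(cj)) / stats::sd(cj)
    stats::cor(z, sp, use = "complete.obs")
  }, numeric(1))
  data.frame(unit = seq_along(spike_times), r = rs, n_windows = nrow(w))
}
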