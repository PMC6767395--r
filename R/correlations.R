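#' Noise correlation of cell pairs within spatial bins
#'
#' Instantaneous firing-rate counts (IFRCs) are taken in fixed windows
#' (250 ms default) during exploration; each window is assigned to the
#' spatial bin (20 x 20 grid over the arena bounding square) containing the
#' window-centre position. For every bin with enough windows the Pearson
#' correlation of the two cells' counts is computed; the pair's noise
#' correlation is the unweighted mean across qualifying bins. Computing
#' within spatial bins removes the spatial (signal) component of the
#' correlation.
#'
#' @param tracking data frame `t`, `x`, `y`
#' @param spike_times list of per-unit spike-time vectors (>= 2 units)
#' @param epoch optional interval data frame
#' @param window_s IFRC window (default 0.25 s)
#' @param n_bins spatial grid per side (default 20)
#' @param min_windows_per_bin bins with fewer windows are ignored (default 5)
#' @param min_bins_per_pair pairs with fewer qualifying bins are excluded
#'   (default 3)
#' @param arena_diameter_cm arena size (default from tracking, then 80)
#' @param partial_speed when TRUE, compute per-bin partial correlations with
#'   the window mean speed partialled out (speed-compensated variant)
#' @return data frame of class `cofiring`: `cell_i`, `cell_j`, `r`,
#'   `n_bins_used`, `n_windows`; attribute `variant`
#' @export
noise_correlation <- function(tracking, spike_times, epoch = NULL,
                              window_s = 0.25, n_bins = 20,
                              min_windows_per_bin = 5, min_bins_per_pair = 3,
                              arena_diameter_cm = NULL,
                              partial_speed = FALSE) {
  n_cells <- length(spike_times)
  if (n_cells < 2) stop("need at least 2 cells")
  if (is.null(arena_diameter_cm)) {
    ar <- attr(tracking, "arena")
    arena_diameter_cm <- if (!is.null(ar)) ar$diameter_cm else 80
  }
  if (is.null(epoch))
    epoch <- iv_new(tracking$t[1], tracking$t[nrow(tracking)])
  w <- iv_windows(epoch, window_s)
  cx <- stats::approx(tracking$t, tracking$x, xout = w$center)$y
  cy <- stats::approx(tracking$t, tracking$y, xout = w$center)$y
  ok <- !is.na(cx) & !is.na(cy)
  w <- w[ok, , drop = FALSE]; cx <- cx[ok]; cy <- cy[ok]
  r_a <- arena_diameter_cm / 2
  edges <- seq(-r_a, r_a, length.out = n_bins + 1)
  bx <- pmin(pmax(findInterval(cx, edges, rightmost.closed = TRUE), 1L), n_bins)
  by <- pmin(pmax(findInterval(cy, edges, rightmost.closed = TRUE), 1L), n_bins)
  bin_id <- (by - 1L) * n_bins + bx
  counts <- count_in_windows(spike_times, w$start, w$end)
  vsp <- if (partial_speed) {
    speed <- tracking_speed(tracking)
    stats::approx(tracking$t, speed, xout = w$center)$y
  } else NULL

  keep_bins <- names(which(table(bin_id) >= min_windows_per_bin))
  by_bin <- split(seq_along(bin_id), bin_id)
  by_bin <- by_bin[keep_bins]

  pairs <- utils::combn(n_cells, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    rs <- vapply(by_bin, function(idx) {
      xi <- counts[idx, i]; xj <- counts[idx, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) return(NA_real_)
      if (!partial_speed) return(stats::cor(xi, xj))
      v <- vsp[idx]
      if (stats::sd(v) == 0) return(stats::cor(xi, xj))
      rxy <- stats::cor(xi, xj); rxv <- stats::cor(xi, v); ryv <- stats::cor(xj, v)
      if (abs(rxv) >= 1 - 1e-12 || abs(ryv) >= 1 - 1e-12) return(NA_real_)
      (rxy - rxv * ryv) / sqrt((1 - rxv^2) * (1 - ryv^2))
    }, numeric(1))
    rs <- rs[!is.na(rs)]
    data.frame(cell_i = i, cell_j = j,
               r = if (length(rs) >= min_bins_per_pair) mean(rs) else NA_real_,
               n_bins_used = length(rs), n_windows = nrow(w))
  })
  out <- do.call(rbind, out)
  attr(out, "variant") <- if (partial_speed) "speed_compensated" else "noise"
  class(out) <- c("cofiring", class(out))
  out
}

#' Speed-compensated noise correlation
#'
#' As [noise_correlation], but each per-bin correlation is the first-order
#' partial correlation `(r_xy - r_xv r_yv) / sqrt((1-r_xv^2)(1-r_yv^2))`
#' with the window mean running speed `v` partialled out. Removes cofiring
#' that is jointly inherited from speed modulation.
#'
#' @inheritParams noise_correlation
#' @export
speed_compensated_noise_correlation <- function(tracking, spike_times,
                                                epoch = NULL, ...) {
  noise_correlation(tracking, spike_times, epoch = epoch,
                    partial_speed = TRUE, ...)
}

#' Stability of a cofiring structure across session halves
#'
#' Pearson correlation, across cell pairs, of the pairwise cofiring values
#' from two halves of an exploration. Group comparisons of two such
#' stability correlations use [fisher_z_test].
#'
#' @param matrix_half1,matrix_half2 `cofiring` data frames over the same
#'   cells (pairs matched by `cell_i`, `cell_j`)
#' @param min_pairs minimum common (non-NA) pairs (default 10)
#' @return list: `r`, `n_pairs`
#' @export
stability_correlation <- function(matrix_half1, matrix_half2, min_pairs = 10) {
  key1 <- paste(matrix_half1$cell_i, matrix_half1$cell_j)
  key2 <- paste(matrix_half2$cell_i, matrix_half2$cell_j)
  common <- intersect(key1, key2)
  r1 <- matrix_half1$r[match(common, key1)]
  r2 <- matrix_half2$r[match(common, key2)]
  ok <- !is.na(r1) & !is.na(r2)
  if (sum(ok) < min_pairs)
    stop("fewer than ", min_pairs, " common pairs with valid correlations")
  list(r = stats::cor(r1[ok], r2[ok]), n_pairs = sum(ok))
}

#' Split an epoch into halves
#'
#' @param epoch single-interval data frame
#' @return list of two interval data frames
#' @export
epoch_halves <- function(epoch) {
  mid <- (epoch$start[1] + epoch$end[1]) / 2
  list(first = iv_new(epoch$start[1], mid), second = iv_new(mid, epoch$end[1]))
}
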