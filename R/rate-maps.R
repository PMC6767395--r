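#' Build an occupancy-normalized firing rate map
#'
#' The arena's bounding square is divided into `n_bins x n_bins` spatial bins
#' (70 x 70 by default, ~1.14 cm bins for an 80 cm arena). Tracking samples
#' and spikes taken while the animal moved slower than the speed filter are
#' discarded; spike positions come from linear interpolation of the tracking
#' at spike times. The raw rate in a bin is spike count / occupancy (s); the
#' smoothed rate applies a 2D Gaussian kernel with mask-aware normalization
#' (kernel weights renormalized over visited bins), so unvisited bins do not
#' drag rates toward zero at field edges.
#'
#' Bin (1,1) sits at the lower-left corner; bin intervals are half-open
#' `[edge_i, edge_{i+1})` with the topmost edge closed.
#'
#' @param tracking data frame `t`, `x`, `y` (cm, arena-centred)
#' @param spike_times numeric vector of spike times (s) for one unit
#' @param epoch optional interval data frame restricting the data
#' @param arena_diameter_cm arena diameter (default from tracking attribute,
#'   then 80)
#' @param n_bins grid size per side (default 70)
#' @param speed_filter_cm_s minimum running speed; samples and spikes below
#'   it are excluded (default 5, `0` disables)
#' @param smooth_sd_bins Gaussian smoothing width in bins (default 2)
#' @return object of class `rate_map`: list with `raw_rate`, `smoothed_rate`,
#'   `occupancy_s`, `spike_count`, `visited` (all `n_bins x n_bins`
#'   matrices; x indexes rows), `bin_edges`, `bin_centers`, `bin_cm`
#' @export
build_rate_map <- function(tracking, spike_times, epoch = NULL,
                           arena_diameter_cm = NULL, n_bins = 70,
                           speed_filter_cm_s = 5, smooth_sd_bins = 2) {
  if (is.null(arena_diameter_cm)) {
    ar <- attr(tracking, "arena")
    arena_diameter_cm <- if (!is.null(ar)) ar$diameter_cm else 80
  }
  dt <- stats::median(diff(tracking$t))
  keep <- rep(TRUE, nrow(tracking))
  if (!is.null(epoch)) keep <- keep & iv_contains(epoch, tracking$t)
  speed <- tracking_speed(tracking)
  if (speed_filter_cm_s > 0) keep <- keep & speed >= speed_filter_cm_s

  st <- spike_times
  if (!is.null(epoch)) st <- st[iv_contains(epoch, st)]
  st <- st[st >= tracking$t[1] & st <= tracking$t[nrow(tracking)]]
  sx <- stats::approx(tracking$t, tracking$x, xout = st)$y
  sy <- stats::approx(tracking$t, tracking$y, xout = st)$y
  if (speed_filter_cm_s > 0 && length(st)) {
    sv <- stats::approx(tracking$t, speed, xout = st)$y
    kk <- sv >= speed_filter_cm_s
    st <- st[kk]; sx <- sx[kk]; sy <- sy[kk]
  }

  r <- arena_diameter_cm / 2
  edges <- seq(-r, r, length.out = n_bins + 1)
  bin_of <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)

  occ <- matrix(0, n_bins, n_bins)
  tx <- tracking$x[keep]; ty <- tracking$y[keep]
  if (length(tx) == 0) stop("no qualifying samples")
  ix <- bin_of(tx); iy <- bin_of(ty)
  occ_tab <- table(factor(ix, levels = 1:n_bins), factor(iy, levels = 1:n_bins))
  occ <- matrix(as.numeric(occ_tab), n_bins, n_bins) * dt

  cnt <- matrix(0, n_bins, n_bins)
  if (length(st)) {
    jx <- bin_of(sx); jy <- bin_of(sy)
    cnt_tab <- table(factor(jx, levels = 1:n_bins), factor(jy, levels = 1:n_bins))
    cnt <- matrix(as.numeric(cnt_tab), n_bins, n_bins)
  }

  visited <- occ > 0
  cnt[!visited] <- 0   # rare spikes interpolated into never-visited bins
  raw <- matrix(0, n_bins, n_bins)
  raw[visited] <- cnt[visited] / occ[visited]

  smoothed <- .smooth_masked(raw, visited, smooth_sd_bins)

  structure(list(raw_rate = raw, smoothed_rate = smoothed,
                 occupancy_s = occ, spike_count = cnt, visited = visited,
                 bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 bin_cm = diff(edges)[1]),
            class = "rate_map")
}

# Gaussian smoothing restricted to visited bins: both the field and the
# visited mask are convolved with the kernel and their ratio taken, so each
# smoothed value is a weighted average over visited bins only.
.smooth_masked <- function(mat, mask, sd_bins) {
  if (sd_bins <= 0) { out <- mat; out[!mask] <- 0; return(out) }
  half <- ceiling(3 * sd_bins)
  g <- stats::dnorm(-half:half, sd = sd_bins)
  g <- g / sum(g)
  conv2sep <- function(m) {
    m2 <- apply(m, 2, function(col) stats::filter(c(rep(0, half), col, rep(0, half)), g, sides = 2)[(half + 1):(half + length(col))])
    t(apply(t(m2), 2, function(row) stats::filter(c(rep(0, half), row, rep(0, half)), g, sides = 2)[(half + 1):(half + length(row))]))
  }
  num <- conv2sep(mat * mask)
  den <- conv2sep(mask * 1)
  out <- matrix(0, nrow(mat), ncol(mat))
  ok <- mask & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate map: %dx%d bins (%.2f cm), %d visited, peak %.2f Hz\n",
              nrow(x$raw_rate), ncol(x$raw_rate), x$bin_cm,
              sum(x$visited), max(x$smoothed_rate)))
  invisible(x)
}

#' Skaggs spatial information (bits per spike)
#'
#' `sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)` over
#' visited bins, where `p_i` is the occupancy share of bin i, `lambda_i` the
#' bin firing rate and `lambda_bar = sum_i p_i lambda_i`; `0 log 0` is 0.
#'
#' @param map a `rate_map`
#' @param use_smoothed compute on the smoothed map (default) or raw
#' @return bits/spike; `NA` with a warning when the mean rate is 0
#' @export
skaggs_information <- function(map, use_smoothed = TRUE) {
  rate <- if (use_smoothed) map$smoothed_rate else map$raw_rate
  v <- map$visited
  p <- map$occupancy_s[v] / sum(map$occupancy_s[v])
  lam <- rate[v]
  lbar <- sum(p * lam)
  if (lbar <= 0) { warning("zero mean rate; information undefined"); return(NA_real_) }
  ok <- lam > 0
  sum(p[ok] * (lam[ok] / lbar) * log2(lam[ok] / lbar))
}

#' Place-field size as a fraction of the covered arena
#'
#' Counts bins whose (smoothed) rate exceeds 0.1 times the map maximum and
#' divides by the number of visited bins.
#'
#' @param map a `rate_map`
#' @param threshold field threshold as a fraction of the peak (default 0.1)
#' @param use_smoothed use the smoothed map (default)
#' @return fraction in [0, 1]; `NA` when the peak rate is 0
#' @export
field_size_fraction <- function(map, threshold = 0.1, use_smoothed = TRUE) {
  rate <- if (use_smoothed) map$smoothed_rate else map$raw_rate
  v <- map$visited
  peak <- max(rate[v])
  if (peak <= 0) return(NA_real_)
  sum(rate[v] > threshold * peak) / sum(v)
}

#' Spatial coherence of a rate map
#'
#' Pearson correlation, over visited bins, between each bin's raw rate and
#' the mean raw rate of its visited 8-neighbours. High coherence means
#' spatially smooth firing; the place-cell criterion requires > 0.5.
#'
#' @param map a `rate_map`
#' @return correlation in [-1, 1]; `NA` for constant maps (fails criterion)
#' @export
map_coherence <- function(map) {
  rate <- map$raw_rate; v <- map$visited
  if (sum(v) < 9) stop("need at least 9 visited bins")
  nb <- nrow(rate)
  num <- matrix(0, nb, nb); den <- matrix(0, nb, nb)
  vm <- v * 1
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sr <- .shift2(rate * vm, di, dj)
    sv <- .shift2(vm, di, dj)
    num <- num + sr
    den <- den + sv
  }
  ok <- v & den > 0
  x <- rate[ok]; y <- num[ok] / den[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

.shift2 <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  si <- max(1, 1 - di):min(n1, n1 - di)
  sj <- max(1, 1 - dj):min(n2, n2 - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

#' Firing sparsity of a rate map
#'
#' `(sum p_i lambda_i)^2 / sum p_i lambda_i^2` over visited bins: 1 for
#' spatially uniform firing, small for compact fields. The place-cell
#' criterion requires < 0.3.
#'
#' @param map a `rate_map`
#' @param use_smoothed use the smoothed map (default)
#' @return sparsity in [0, 1]; `NA` when the mean rate is 0
#' @export
map_sparsity <- function(map, use_smoothed = TRUE) {
  rate <- if (use_smoothed) map$smoothed_rate else map$raw_rate
  v <- map$visited
  p <- map$occupancy_s[v] / sum(map$occupancy_s[v])
  lam <- rate[v]
  m1 <- sum(p * lam); m2 <- sum(p * lam^2)
  if (m2 <= 0) { warning("zero mean rate; sparsity undefined"); return(NA_real_) }
  m1^2 / m2
}

#' Place-cell statistics and selection
#'
#' Bundles the spatial statistics of one unit's rate map and applies the
#' place-cell criteria: coherence > 0.5 and sparsity < 0.3.
#'
#' @param map a `rate_map`
#' @return one-row data frame: `spatial_info_bits_per_spike`,
#'   `field_size_fraction`, `coherence`, `sparsity`, `peak_rate_hz`,
#'   `is_place_cell`
#' @export
place_cell_stats <- function(map) {
  coh <- map_coherence(map)
  spa <- suppressWarnings(map_sparsity(map))
  data.frame(
    spatial_info_bits_per_spike = suppressWarnings(skaggs_information(map)),
    field_size_fraction = field_size_fraction(map),
    coherence = coh,
    sparsity = spa,
    peak_rate_hz = max(map$smoothed_rate[map$visited]),
    is_place_cell = !is.na(coh) && !is.na(spa) && coh > 0.5 && spa < 0.3
  )
}

#' Rate remapping score between two conditions
#'
#' `|FR_C1 - FR_C2| / (FR_C1 + FR_C2)` on a cell's mean firing rates in two
#' conditions; in [0, 1], with 0 = identical rates and 1 = firing in one
#' condition only. Undefined (NA) when both rates are 0 -- such cells are
#' excluded from population summaries.
#'
#' @param fr_c1,fr_c2 mean firing rates (Hz) in the two conditions
#' @return score, vectorized over inputs
#' @export
remapping_score <- function(fr_c1, fr_c2) {
  s <- fr_c1 + fr_c2
  out <- abs(fr_c1 - fr_c2) / s
  out[s <= 0] <- NA_real_
  out
}
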