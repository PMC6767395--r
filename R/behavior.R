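#' Windowed movement speed
#'
#' Movement speed is computed from the distances travelled between consecutive
#' 25.6 ms tracking samples: each block of 10 consecutive distances (256 ms)
#' is averaged with zero distances excluded from the mean -- this suppresses
#' tracker dropouts and genuine immobility samples -- and the average distance
#' is converted to a speed by the sampling rate. A block whose distances are
#' all zero scores 0 cm/s.
#'
#' @param tracking data frame `t`, `x`, `y` sampled at a fixed interval
#' @return data frame `t` (window centre, s), `speed_cm_s`; attribute
#'   `mean_speed_cm_s` carries the session mean (mean of window values)
#' @export
windowed_speed <- function(tracking) {
  n <- nrow(tracking)
  if (n < 11) stop("need at least 11 tracking samples")
  dt <- stats::median(diff(tracking$t))
  d <- sqrt(diff(tracking$x)^2 + diff(tracking$y)^2)
  n_win <- floor(length(d) / 10)
  idx <- matrix(seq_len(n_win * 10), nrow = 10)
  speed <- apply(idx, 2, function(i) {
    di <- d[i]
    nz <- di[di > 0]
    if (length(nz) == 0) 0 else mean(nz) / dt
  })
  t_mid <- tracking$t[1] + (seq_len(n_win) - 0.5) * 10 * dt
  out <- data.frame(t = t_mid, speed_cm_s = speed)
  attr(out, "mean_speed_cm_s") <- mean(speed)
  out
}

#' Immobility fraction
#'
#' Fraction of non-overlapping 1-s windows (aligned to the start of the
#' tracking record) in which the total distance travelled is below 2 cm.
#'
#' @param tracking data frame `t`, `x`, `y`
#' @param window_s window length (s)
#' @param threshold_cm distance threshold (cm)
#' @return scalar fraction in [0, 1]
#' @export
immobility_fraction <- function(tracking, window_s = 1, threshold_cm = 2) {
  span <- tracking$t[nrow(tracking)] - tracking$t[1]
  if (span < window_s) stop("need at least one full window of tracking")
  d <- c(0, sqrt(diff(tracking$x)^2 + diff(tracking$y)^2))
  win <- floor((tracking$t - tracking$t[1]) / window_s)
  full <- floor(span / window_s)
  keep <- win < full
  dist_per_win <- tapply(d[keep], win[keep], sum)
  mean(dist_per_win < threshold_cm)
}

#' Arena coverage deficit
#'
#' Tracking positions are binned at 5 cm over the arena's bounding square.
#' Empty bins are split into out-of-arena and unvisited-in-arena bins by a
#' neighbourhood rule: an empty bin surrounded by fewer than 5 empty bins
#' (8-connected neighbourhood, boundary cells padded as empty) lies inside
#' the arena and counts as a nonvisited area. The deficit is the fraction of
#' nonvisited bins over all bins within the open field (visited + nonvisited).
#'
#' @param tracking data frame `t`, `x`, `y` (cm, arena-centred)
#' @param arena_diameter_cm arena diameter; defaults to the tracking
#'   attribute, then 80 cm
#' @param bin_cm spatial bin size (default 5 cm)
#' @return scalar uncovered fraction in [0, 1]; attributes `n_visited`,
#'   `n_unvisited`
#' @export
coverage_deficit <- function(tracking, arena_diameter_cm = NULL, bin_cm = 5) {
  if (is.null(arena_diameter_cm)) {
    ar <- attr(tracking, "arena")
    arena_diameter_cm <- if (!is.null(ar)) ar$diameter_cm else 80
  }
  r <- arena_diameter_cm / 2
  edges <- seq(-r, r, by = bin_cm)
  if (edges[length(edges)] < r) edges <- c(edges, edges[length(edges)] + bin_cm)
  nb <- length(edges) - 1L
  ix <- findInterval(tracking$x, edges, rightmost.closed = TRUE)
  iy <- findInterval(tracking$y, edges, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb
  visited <- matrix(FALSE, nb, nb)
  visited[cbind(ix[ok], iy[ok])] <- TRUE

  empty <- !visited
  # count empty 8-neighbours of each empty bin; outside the grid counts empty
  pad <- matrix(TRUE, nb + 2, nb + 2)
  pad[2:(nb + 1), 2:(nb + 1)] <- empty
  nbr <- matrix(0L, nb, nb)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbr <- nbr + pad[2:(nb + 1) + di, 2:(nb + 1) + dj]
  }
  unvisited_in_arena <- empty & nbr < 5
  n_vis <- sum(visited); n_unvis <- sum(unvisited_in_arena)
  out <- n_unvis / (n_vis + n_unvis)
  attr(out, "n_visited") <- n_vis
  attr(out, "n_unvisited") <- n_unvis
  out
}

#' Session behaviour summary
#'
#' @param tracking data frame `t`, `x`, `y`
#' @param arena_diameter_cm arena diameter (cm)
#' @return one-row data frame: `mean_speed_cm_s`, `immobility_fraction`,
#'   `uncovered_fraction`
#' @export
behavior_summary <- function(tracking, arena_diameter_cm = NULL) {
  ws <- windowed_speed(tracking)
  data.frame(
    mean_speed_cm_s = attr(ws, "mean_speed_cm_s"),
    immobility_fraction = immobility_fraction(tracking),
    uncovered_fraction = as.numeric(coverage_deficit(tracking, arena_diameter_cm))
  )
}
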