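#' Bayesian position decoding from population spike counts
#'
#' Reconstructs the animal's position from place-cell population vectors in
#' sliding windows (250 ms, stepped 125 ms). With a uniform spatial prior
#' P(x) and conditionally independent Poisson spike counts given position,
#' the posterior over visited spatial bins is
#' `P(x|n) = P(n|x) P(x) / P(n)`, computed in the log domain:
#' `log P(n|x) = sum_c [n_c log(lambda_c(x) tau) - lambda_c(x) tau -
#' log(n_c!)]` with `tau` the window length and rates floored at `rate_floor`
#' to avoid log 0. The normalizer P(n) makes the posterior sum to 1. The
#' decoded position is the centre of the maximum-probability bin (row-major
#' first index on ties); the error is the Euclidean distance to the true
#' (interpolated) position at the window centre.
#'
#' Rate maps are built over the whole epoch being decoded (no
#' cross-validation) unless `maps` are supplied; windows with zero total
#' spikes are skipped. By default decoding windows obey the same 5 cm/s
#' speed filter as the maps (window-centre speed).
#'
#' @param tracking data frame `t`, `x`, `y`
#' @param spike_times list of per-unit spike-time vectors (place cells)
#' @param epoch interval data frame to decode
#' @param maps optional list of `rate_map`s (one per unit); built from the
#'   epoch when `NULL`
#' @param window_s,step_s decoding window and step (s)
#' @param rate_floor_hz minimum rate used in the likelihood (default 0.01)
#' @param speed_filter_cm_s drop windows whose centre speed is below this
#'   (default 5; 0 disables)
#' @param n_bins,smooth_sd_bins passed to [build_rate_map] when maps are built
#' @return list of class `decoder_result`: `windows` (data frame: `t`,
#'   `decoded_x`, `decoded_y`, `true_x`, `true_y`, `error_cm`, `n_spikes`),
#'   `posterior` (windows x visited-bins matrix), `bin_xy` (visited-bin
#'   centres), `maps`
#' @export
decode_position <- function(tracking, spike_times, epoch = NULL, maps = NULL,
                            window_s = 0.25, step_s = 0.125,
                            rate_floor_hz = 0.01, speed_filter_cm_s = 5,
                            n_bins = 70, smooth_sd_bins = 2) {
  if (length(spike_times) == 0) stop("no place cells to decode from")
  if (is.null(epoch))
    epoch <- iv_new(tracking$t[1], tracking$t[nrow(tracking)])
  if (is.null(maps))
    maps <- lapply(spike_times, function(st)
      build_rate_map(tracking, st, epoch = epoch, n_bins = n_bins,
                     speed_filter_cm_s = speed_filter_cm_s,
                     smooth_sd_bins = smooth_sd_bins))
  visited <- Reduce(`|`, lapply(maps, function(m) m$visited))
  vi <- which(visited)                       # column-major linear indices
  n_v <- length(vi)
  centers <- maps[[1]]$bin_centers
  nb <- length(centers)
  bx <- centers[(vi - 1L) %% nb + 1L]
  by <- centers[(vi - 1L) %/% nb + 1L]

  # rates x cells, floored
  lam <- vapply(maps, function(m) pmax(m$smoothed_rate[vi], rate_floor_hz),
                numeric(n_v))
  log_lam_tau <- log(lam * window_s)
  lam_tau_sum <- rowSums(lam) * window_s     # per-bin sum over cells

  w <- iv_windows(epoch, window_s, step_s)
  keep <- w$center >= tracking$t[1] & w$center <= tracking$t[nrow(tracking)]
  w <- w[keep, , drop = FALSE]
  if (speed_filter_cm_s > 0) {
    speed <- tracking_speed(tracking)
    vs <- stats::approx(tracking$t, speed, xout = w$center)$y
    w <- w[vs >= speed_filter_cm_s, , drop = FALSE]
  }
  counts <- count_in_windows(spike_times, w$start, w$end)
  tot <- rowSums(counts)
  w <- w[tot > 0, , drop = FALSE]
  counts <- counts[tot > 0, , drop = FALSE]
  if (nrow(w) == 0) stop("no decodable windows (all zero-spike)")

  # log posterior: windows x bins
  ll <- counts %*% t(log_lam_tau)
  ll <- sweep(ll, 2, lam_tau_sum, `-`)
  ll <- ll - rowSums(lgamma(counts + 1))
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)

  amax <- apply(ll, 1, which.max)            # first index on ties
  dx <- bx[amax]; dy <- by[amax]
  tx <- stats::approx(tracking$t, tracking$x, xout = w$center)$y
  ty <- stats::approx(tracking$t, tracking$y, xout = w$center)$y
  err <- sqrt((dx - tx)^2 + (dy - ty)^2)

  structure(list(
    windows = data.frame(t = w$center, decoded_x = dx, decoded_y = dy,
                         true_x = tx, true_y = ty, error_cm = err,
                         n_spikes = rowSums(counts)),
    posterior = post, bin_xy = cbind(x = bx, y = by), maps = maps),
    class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  s <- decoding_error_summary(x)
  cat(sprintf("decoder: %d windows, median error %.2f cm, mean %.2f cm\n",
              s$n_windows, s$median_error_cm, s$mean_error_cm))
  invisible(x)
}

#' Summary of decoding errors
#'
#' @param decoded a `decoder_result` (or a data frame with `error_cm`)
#' @return one-row data frame: `median_error_cm`, `mean_error_cm`,
#'   `n_windows`
#' @export
decoding_error_summary <- function(decoded) {
  err <- if (inherits(decoded, "decoder_result")) decoded$windows$error_cm
         else decoded$error_cm
  if (length(err) == 0) stop("no decoded windows")
  data.frame(median_error_cm = stats::median(err),
             mean_error_cm = mean(err), n_windows = length(err))
}
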