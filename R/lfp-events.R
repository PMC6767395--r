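#' Detect theta epochs by the theta/delta power ratio
#'
#' The pyramidal-layer LFP is analyzed in 1600-ms segments stepped by
#' 800 ms. For each segment a multitaper power spectrum (Thomson's method,
#' NW = 3, 5 tapers) gives the ratio of mean power in the theta band
#' (6-10 Hz) to the delta band (2-4 Hz); segments at or above the threshold
#' ratio are marked theta and adjacent marked segments are merged.
#'
#' @param lfp an [lfp_new] object
#' @param epoch interval data frame to scan
#' @param ratio_threshold theta/delta ratio marking a theta segment
#'   (default 2)
#' @param segment_s,step_s segment length and step (s)
#' @param theta_band,delta_band frequency bands (Hz)
#' @return interval data frame `start`, `end`, plus `peak_ratio` per merged
#'   interval; empty (with a warning) when the epoch is shorter than one
#'   segment
#' @export
detect_theta_epochs <- function(lfp, epoch, ratio_threshold = 2,
                                segment_s = 1.6, step_s = 0.8,
                                theta_band = c(6, 10), delta_band = c(2, 4)) {
  x <- lfp_channel(lfp, "pyramidal_layer")
  t <- lfp_times(lfp)
  seg <- iv_windows(epoch, segment_s, step_s)
  if (nrow(seg) == 0) {
    warning("epoch shorter than one segment; no theta detection")
    return(cbind(iv_new(), data.frame(peak_ratio = numeric(0))))
  }
  nseg <- round(segment_s * lfp$fs)
  ratio <- vapply(seq_len(nrow(seg)), function(i) {
    i0 <- which.min(abs(t - seg$start[i]))
    if (i0 + nseg - 1 > length(x)) return(NA_real_)
    p <- multitaper_psd(x[i0:(i0 + nseg - 1)], lfp$fs)
    th <- mean(p$power[p$freq_hz >= theta_band[1] & p$freq_hz <= theta_band[2]])
    de <- mean(p$power[p$freq_hz >= delta_band[1] & p$freq_hz <= delta_band[2]])
    th / de
  }, numeric(1))
  hit <- !is.na(ratio) & ratio >= ratio_threshold
  if (!any(hit)) return(cbind(iv_new(), data.frame(peak_ratio = numeric(0))))
  iv <- iv_merge(iv_new(seg$start[hit], seg$end[hit]))
  iv$peak_ratio <- vapply(seq_len(nrow(iv)), function(k) {
    max(ratio[hit][seg$start[hit] >= iv$start[k] & seg$end[hit] <= iv$end[k]])
  }, numeric(1))
  iv
}

#' Instantaneous theta phase of the LFP
#'
#' Zero-phase band-pass (5-28 Hz) of the pyramidal-layer channel followed by
#' the analytic-signal phase: 0 deg at the filtered-signal positive peak,
#' increasing with time, in [0, 360).
#'
#' @param lfp an [lfp_new] object
#' @param band filter band (Hz), default `c(5, 28)`
#' @return data frame `t`, `phase_deg`
#' @export
theta_phase <- function(lfp, band = c(5, 28)) {
  x <- bandpass(lfp_channel(lfp, "pyramidal_layer"), lfp$fs, band)
  data.frame(t = lfp_times(lfp), phase_deg = analytic_phase_deg(x))
}

#' Detect gamma epochs by band-limited RMS power
#'
#' The LFP is filtered in the gamma band (30-80 Hz); RMS amplitude in
#' sliding 25-ms windows is thresholded at `z_threshold` SDs above the
#' epoch mean.
#'
#' @param lfp an [lfp_new] object
#' @param epoch interval data frame to scan
#' @param z_threshold threshold in SD units (default 2)
#' @param band gamma band (Hz)
#' @param rms_window_s RMS window (s)
#' @return interval data frame `start`, `end`, `peak_z`
#' @export
detect_gamma_epochs <- function(lfp, epoch, z_threshold = 2,
                                band = c(30, 80), rms_window_s = 0.025) {
  x <- bandpass(lfp_channel(lfp, "pyramidal_layer"), lfp$fs, band)
  t <- lfp_times(lfp)
  rms <- moving_rms(x, lfp$fs, rms_window_s)
  inside <- iv_contains(epoch, t)
  mu <- mean(rms[inside]); sdv <- stats::sd(rms[inside])
  if (sdv == 0) return(cbind(iv_new(), data.frame(peak_z = numeric(0))))
  z <- (rms - mu) / sdv
  .threshold_events(t, z, inside, z_threshold, boundary = z_threshold,
                    min_dur = 0, merge_gap = 0)
}

#' Detect sharp-wave ripples
#'
#' The reference channel is subtracted from each pyramidal-layer channel
#' (cancelling common-mode artifacts) before band-pass filtering at
#' 150-250 Hz; the moving-RMS power is summed across pyramidal-layer
#' channels. Baseline mean and SD are frozen from the first sleep epoch.
#' The background statistics are estimated from sub-threshold samples
#' (samples more than 4 robust SDs above the median -- the events
#' themselves -- are excluded before taking the background mean and SD, so
#' event density does not inflate the threshold). Events exceed
#' `z_threshold` (7) SDs, have their boundaries extended out to the
#' `boundary_z` (2) SD crossings, are merged across gaps shorter than
#' `merge_gap_s` and discarded when shorter than `min_duration_s`; each
#' event's centre is its peak-power time.
#'
#' @param lfp an [lfp_new] object with a `reference_above_layer` channel
#' @param sleep_epochs interval data frame of sleep epochs (>= 1 row); the
#'   first row sets the baseline
#' @param z_threshold,boundary_z detection and boundary thresholds (SD)
#' @param band ripple band (Hz)
#' @param rms_window_s RMS window (s)
#' @param min_duration_s,merge_gap_s post-processing parameters (s)
#' @return data frame `start`, `end`, `t` (peak-power centre), `peak_z`
#' @export
detect_swrs <- function(lfp, sleep_epochs, z_threshold = 7, boundary_z = 2,
                        band = c(150, 250), rms_window_s = 0.025,
                        min_duration_s = 0.03, merge_gap_s = 0.05) {
  if (nrow(sleep_epochs) == 0) stop("no sleep epoch provided")
  ref <- lfp_channel(lfp, "reference_above_layer")
  pyr_idx <- which(lfp$roles == "pyramidal_layer")
  t <- lfp_times(lfp)
  pow <- 0
  for (i in pyr_idx) {
    f <- bandpass(lfp$channels[, i] - ref, lfp$fs, band)
    pow <- pow + moving_rms(f, lfp$fs, rms_window_s)
  }
  first <- iv_contains(sleep_epochs[1, , drop = FALSE], t)
  med <- stats::median(pow[first]); madv <- stats::mad(pow[first])
  bg <- first & pow <= med + 4 * madv
  mu <- mean(pow[bg]); sdv <- stats::sd(pow[bg])
  z <- (pow - mu) / sdv
  inside <- iv_contains(sleep_epochs, t)
  ev <- .threshold_events(t, z, inside, z_threshold, boundary = boundary_z,
                          min_dur = min_duration_s, merge_gap = merge_gap_s)
  names(ev)[names(ev) == "peak_t"] <- "t"
  ev
}

# Shared run-based event extraction on a z-scored series.
.threshold_events <- function(t, z, inside, threshold, boundary,
                              min_dur, merge_gap) {
  hit <- inside & z >= threshold
  if (!any(hit)) {
    out <- iv_new()
    out$t <- numeric(0); out$peak_z <- numeric(0)
    return(out)
  }
  above_b <- inside & z >= boundary
  r <- rle(above_b)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  # keep boundary-level runs that contain at least one detection-level sample
  keep <- r$values & vapply(seq_along(r$values), function(k)
    r$values[k] && any(hit[starts[k]:ends[k]]), logical(1))
  iv <- iv_new(t[starts[keep]], t[ends[keep]])
  if (merge_gap > 0) iv <- iv_merge(iv, gap = merge_gap)
  dur_ok <- (iv$end - iv$start) >= min_dur
  iv <- iv[dur_ok, , drop = FALSE]
  if (nrow(iv) == 0) {
    out <- iv_new(); out$t <- numeric(0); out$peak_z <- numeric(0)
    return(out)
  }
  stats_ev <- t(vapply(seq_len(nrow(iv)), function(k) {
    idx <- which(t >= iv$start[k] & t <= iv$end[k])
    pk <- idx[which.max(z[idx])]
    c(t[pk], z[pk])
  }, numeric(2)))
  iv$t <- stats_ev[, 1]
  iv$peak_z <- stats_ev[, 2]
  names(iv)[names(iv) == "t"] <- "peak_t"
  iv
}

#' Theta-phase locking of gamma cycle peaks
#'
#' Locates the peak of every gamma cycle (local maxima of the 30-80 Hz
#' band-filtered signal) occurring during gamma periods; peaks falling
#' inside theta epochs have the theta phase at their time extracted, and
#' the circular mean of those phases gives the preferred theta angle of
#' gamma. Restricting to detected gamma periods matters: outside bursts the
#' band-filtered trace is noise whose cycle peaks tile theta phase
#' uniformly and would wash out the locking.
#'
#' @param lfp an [lfp_new] object
#' @param theta_epochs interval data frame of theta periods
#' @param gamma_epochs optional interval data frame of gamma periods;
#'   detected with [detect_gamma_epochs] over the theta epochs when `NULL`
#' @param phase optional precomputed [theta_phase] series
#' @param band gamma band (Hz)
#' @return list: `angle_deg`, `length`, `n_peaks`, `phases_deg`; empty
#'   (with warning) when no gamma peak falls inside a theta epoch
#' @export
gamma_peak_theta_locking <- function(lfp, theta_epochs, gamma_epochs = NULL,
                                     phase = NULL, band = c(30, 80)) {
  g <- bandpass(lfp_channel(lfp, "pyramidal_layer"), lfp$fs, band)
  t <- lfp_times(lfp)
  if (is.null(gamma_epochs))
    gamma_epochs <- detect_gamma_epochs(lfp, theta_epochs, band = band)
  pk <- which(diff(sign(diff(g))) == -2) + 1L
  pk <- pk[iv_contains(theta_epochs, t[pk]) &
             iv_contains(gamma_epochs, t[pk])]
  if (length(pk) == 0) {
    warning("no gamma peaks inside theta epochs")
    return(list(angle_deg = NA_real_, length = NA_real_, n_peaks = 0L,
                phases_deg = numeric(0)))
  }
  if (is.null(phase)) phase <- theta_phase(lfp)
  un <- .unwrap_deg(phase$phase_deg)
  ph <- stats::approx(phase$t, un, xout = t[pk])$y %% 360
  mv <- circ_mean_vector(ph)
  list(angle_deg = mv$angle_deg, length = mv$length, n_peaks = length(pk),
       phases_deg = ph)
}
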