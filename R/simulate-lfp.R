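#' Simulate a theta phase series
#'
#' Integrates an instantaneous frequency that wanders inside the theta band
#' (OU process around its centre), giving a phase series suitable both for
#' building the LFP theta component (`cos(phase)`) and for phase-modulating
#' spike generators. Phase 0 deg is the oscillation peak.
#'
#' @param t0,t1 span (s)
#' @param fs sampling rate (Hz)
#' @param f_range frequency band (Hz), default 6-10
#' @param tau_s frequency wander time constant
#' @param seed optional seed (local RNG)
#' @return data frame `t`, `phase_deg` (wrapped to [0, 360)), `freq_hz`
#' @export
generate_theta_phase <- function(t0, t1, fs = 1250, f_range = c(6, 10),
                                 tau_s = 2, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  t <- seq(t0, t1, by = 1 / fs)
  n <- length(t)
  f0 <- mean(f_range); fsd <- diff(f_range) / 4
  a <- exp(-1 / (fs * tau_s))
  innov <- stats::rnorm(n) * fsd * sqrt(1 - a^2)
  dev <- stats::filter(innov, a, method = "recursive")
  f <- pmin(pmax(f0 + as.numeric(dev), f_range[1]), f_range[2])
  phase <- cumsum(2 * pi * f / fs)
  data.frame(t = t, phase_deg = (phase * 180 / pi) %% 360, freq_hz = f)
}

#' Simulate a two-channel CA1 LFP
#'
#' Builds a pyramidal-layer channel and an above-layer reference channel
#' over a session. Both carry shared pink noise plus independent broadband
#' noise. During exploration and REM intervals the pyramidal channel adds a
#' theta oscillation (`cos` of the supplied phase series) and a gamma
#' component whose amplitude is gated at a fixed theta phase (von Mises
#' gate), producing one gamma burst per theta cycle. During NREM intervals
#' it adds strong delta-band noise, and sharp-wave-ripple transients
#' (150-250 Hz carrier under a Hanning envelope) are injected at the given
#' times on the pyramidal channel only. Transient amplitudes are calibrated
#' against the reference-subtracted ripple-band background so each event's
#' peak moving-RMS sits `swr_z` SDs above the background mean.
#'
#' @param states data frame `label`, `start`, `end`; labels in
#'   `{explore, rem, nrem, rest}`
#' @param theta_phase data frame from [generate_theta_phase] covering the
#'   session span (required when any explore/rem state exists)
#' @param fs sampling rate (Hz, >= 1000)
#' @param swr_times SWR centre times (s); must lie inside `nrem` states
#' @param swr_z target ripple-band z-score of injected transients
#' @param swr_dur_range_s envelope duration range (s)
#' @param gamma_gate_phase_deg theta phase of maximal gamma amplitude
#' @param gamma_kappa concentration of the gamma amplitude gate
#' @param gamma_freq_hz gamma carrier frequency (Hz)
#' @param theta_amp,gamma_amp,delta_amp,noise_amp,common_amp component
#'   amplitudes (arbitrary units)
#' @param gamma_bursts optional data frame `t`, `z`: extra discrete gamma
#'   bursts (100 ms Hanning envelope) calibrated to `z` SDs of the
#'   gamma-band moving-RMS background
#' @param common_artifacts optional data frame `t`, `amp`: transients added
#'   identically to both channels (for common-mode rejection tests);
#'   60 Hz-band tone bursts
#' @param seed optional seed (local RNG)
#' @return an [lfp_new] object; attribute `swr_truth` holds the injected
#'   event table (`t`, `duration_s`)
#' @export
generate_lfp <- function(states, theta_phase = NULL, fs = 1250,
                         swr_times = numeric(0), swr_z = 10,
                         swr_dur_range_s = c(0.05, 0.1),
                         gamma_gate_phase_deg = 240, gamma_kappa = 2,
                         gamma_freq_hz = 55,
                         theta_amp = 1, gamma_amp = 0.25, delta_amp = 0.8,
                         noise_amp = 0.2, common_amp = 0.3,
                         gamma_bursts = NULL, common_artifacts = NULL,
                         seed = NULL) {
  if (fs < 1000) stop("fs must be at least 1000 Hz")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  t0 <- min(states$start); t1 <- max(states$end)
  n <- round((t1 - t0) * fs) + 1L
  t <- t0 + (seq_len(n) - 1L) / fs

  nrem_iv <- iv_merge(states[states$label == "nrem", c("start", "end")])
  osc_iv <- iv_merge(states[states$label %in% c("explore", "rem"),
                            c("start", "end")])
  if (length(swr_times) && !all(iv_contains(nrem_iv, swr_times)))
    stop("SWR times must lie inside nrem sleep states")
  if (nrow(osc_iv) > 0 && is.null(theta_phase))
    stop("theta_phase required for explore/rem states")

  common <- .pink_noise(n) * common_amp
  pyr <- common + stats::rnorm(n) * noise_amp
  ref <- common + stats::rnorm(n) * noise_amp

  if (nrow(osc_iv) > 0) {
    in_osc <- iv_contains(osc_iv, t)
    ph_un <- .unwrap_deg(theta_phase$phase_deg)
    ph <- stats::approx(theta_phase$t, ph_un, xout = t[in_osc], rule = 2)$y
    theta_sig <- theta_amp * cos(deg2rad(ph))
    gate <- exp(gamma_kappa * cos(deg2rad(ph - gamma_gate_phase_deg))) /
      besselI(gamma_kappa, 0)
    gamma_sig <- gamma_amp * gate * cos(2 * pi * gamma_freq_hz * t[in_osc])
    pyr[in_osc] <- pyr[in_osc] + theta_sig + gamma_sig
  }
  if (nrow(nrem_iv) > 0) {
    in_nrem <- iv_contains(nrem_iv, t)
    delta <- bandpass(stats::rnorm(n), fs, c(2, 4))
    delta <- delta / stats::sd(delta) * delta_amp
    pyr[in_nrem] <- pyr[in_nrem] + delta[in_nrem]
    ref[in_nrem] <- ref[in_nrem] + 0.5 * delta[in_nrem]
  }
  if (!is.null(common_artifacts)) {
    for (i in seq_len(nrow(common_artifacts))) {
      idx <- .env_idx(t, common_artifacts$t[i], 0.1, fs)
      burst <- common_artifacts$amp[i] * .hann_env(length(idx)) *
        cos(2 * pi * 60 * t[idx])
      pyr[idx] <- pyr[idx] + burst
      ref[idx] <- ref[idx] + burst
    }
  }

  swr_truth <- NULL
  if (length(swr_times)) {
    # ripple-band background stats of the reference-subtracted signal
    bg <- moving_rms(bandpass(pyr - ref, fs, c(150, 250)), fs, 0.025)
    in_nrem <- iv_contains(nrem_iv, t)
    mu <- mean(bg[in_nrem]); sdv <- stats::sd(bg[in_nrem])
    target_rms <- sqrt(pmax((mu + swr_z * sdv)^2 - mu^2, 0))
    durs <- stats::runif(length(swr_times), swr_dur_range_s[1], swr_dur_range_s[2])
    f_rip <- stats::runif(length(swr_times), 160, 240)
    for (i in seq_along(swr_times)) {
      idx <- .env_idx(t, swr_times[i], durs[i], fs)
      env <- .hann_env(length(idx))
      burst <- env * cos(2 * pi * f_rip[i] * (t[idx] - swr_times[i]))
      # scale against the local noise so the realized ripple-band peak
      # z-score equals swr_z exactly (the burst/noise cross term would
      # otherwise disperse realized amplitudes by ~1.4 SD)
      s <- .calibrate_burst_scale(pyr - ref, idx, burst, fs, c(150, 250),
                                  mu + swr_z * sdv, target_rms)
      pyr[idx] <- pyr[idx] + s * burst
    }
    swr_truth <- data.frame(t = swr_times, duration_s = durs)
  }
  if (!is.null(gamma_bursts) && nrow(gamma_bursts)) {
    bgg <- moving_rms(bandpass(pyr, fs, c(30, 80)), fs, 0.025)
    use <- if (nrow(osc_iv)) iv_contains(osc_iv, t) else rep(TRUE, n)
    mug <- mean(bgg[use]); sdg <- stats::sd(bgg[use])
    # burst carriers kept >= 7 Hz away from the gated background carrier so
    # slow beats cannot null a whole burst
    f_lo <- stats::runif(nrow(gamma_bursts), 35, gamma_freq_hz - 7)
    f_hi <- stats::runif(nrow(gamma_bursts), gamma_freq_hz + 7, 75)
    f_b <- ifelse(stats::runif(nrow(gamma_bursts)) < 0.5, f_lo, f_hi)
    for (i in seq_len(nrow(gamma_bursts))) {
      idx <- .env_idx(t, gamma_bursts$t[i], 0.1, fs)
      target <- sqrt(pmax((mug + gamma_bursts$z[i] * sdg)^2 - mug^2, 0))
      burst <- .hann_env(length(idx)) *
        cos(2 * pi * f_b[i] * (t[idx] - gamma_bursts$t[i]))
      s <- .calibrate_burst_scale(pyr, idx, burst, fs, c(30, 80),
                                  mug + gamma_bursts$z[i] * sdg, target)
      pyr[idx] <- pyr[idx] + s * burst
    }
  }

  out <- lfp_new(cbind(pyr, ref), fs = fs, t0 = t0,
                 roles = c("pyramidal_layer", "reference_above_layer"))
  attr(out, "swr_truth") <- swr_truth
  out
}

# Peak moving-RMS of a unit burst after band-pass filtering (zero padding
# around the burst so the filter transient settles).
.burst_peak_rms <- function(burst, fs, band) {
  pad <- round(0.25 * fs)
  x <- c(numeric(pad), burst, numeric(pad))
  max(moving_rms(bandpass(x, fs, band), fs, 0.025))
}

# Scale factor for an injected burst such that the realized band-limited
# peak moving-RMS of noise + scale*burst hits `target_peak`, accounting for
# the local noise under the event. Secant iteration from the noise-free
# solution `target_rms / burst_peak_rms`.
.calibrate_burst_scale <- function(noise, idx, burst, fs, band,
                                   target_peak, target_rms) {
  pad <- round(0.3 * fs)
  lo <- max(1, idx[1] - pad); hi <- min(length(noise), idx[length(idx)] + pad)
  seg <- noise[lo:hi]
  bseg <- numeric(hi - lo + 1)
  bseg[(idx - lo + 1)] <- burst
  core <- (idx - lo + 1)
  realized <- function(s) {
    r <- moving_rms(bandpass(seg + s * bseg, fs, band), fs, 0.025)
    max(r[core])
  }
  s0 <- target_rms / .burst_peak_rms(burst, fs, band)
  f0 <- realized(s0) - target_peak
  s1 <- s0 * (1 + ifelse(f0 > 0, -0.1, 0.1))
  f1 <- realized(s1) - target_peak
  for (k in 1:3) {
    if (abs(f1) < 1e-4 * target_peak || f1 == f0) break
    s2 <- s1 - f1 * (s1 - s0) / (f1 - f0)
    s2 <- max(s2, 0)
    s0 <- s1; f0 <- f1
    s1 <- s2; f1 <- realized(s1) - target_peak
  }
  s1
}

.env_idx <- function(t, center, dur, fs) {
  half <- dur / 2
  which(t >= center - half & t <= center + half)
}

.hann_env <- function(m) {
  if (m < 3) return(rep(1, m))
  0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
}

# 1/f amplitude noise via spectral shaping, unit variance; works on a
# power-of-two grid (arbitrary lengths can hit the FFT's slow prime paths)
.pink_noise <- function(n) {
  m <- stats::nextn(n, 2)
  X <- stats::fft(stats::rnorm(m))
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE) / m)[seq_len(n)]
  x / stats::sd(x)
}
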