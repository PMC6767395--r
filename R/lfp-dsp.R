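#' LFP container
#'
#' LFP recordings are lists with `fs` (Hz), `t0` (s), and `channels`, a
#' samples x channels numeric matrix with a `roles` character vector
#' (`"pyramidal_layer"`, `"reference_above_layer"`).
#'
#' @param channels samples x channels matrix (or vector for one channel)
#' @param fs sampling rate (Hz)
#' @param t0 time of the first sample (s)
#' @param roles channel roles
#' @export
lfp_new <- function(channels, fs, t0 = 0, roles = NULL) {
  if (is.null(dim(channels))) channels <- matrix(channels, ncol = 1)
  if (is.null(roles)) roles <- rep("pyramidal_layer", ncol(channels))
  stopifnot(length(roles) == ncol(channels), fs > 0)
  structure(list(channels = channels, fs = fs, t0 = t0, roles = roles),
            class = "lfp")
}

#' @export
print.lfp <- function(x, ...) {
  cat(sprintf("lfp: %d channels (%s), %.1f s at %g Hz\n", ncol(x$channels),
              paste(x$roles, collapse = ", "), nrow(x$channels) / x$fs, x$fs))
  invisible(x)
}

lfp_times <- function(lfp) lfp$t0 + (seq_len(nrow(lfp$channels)) - 1) / lfp$fs

lfp_channel <- function(lfp, role) {
  i <- which(lfp$roles == role)
  if (length(i) == 0) stop("no channel with role ", role)
  lfp$channels[, i, drop = TRUE]
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR design ([signal::fir1]) with order set by a
#' 3-cycles-at-the-low-edge rule, applied with exactly zero phase by
#' multiplying the signal spectrum with the filter's squared magnitude
#' response (the frequency-domain equivalent of forward-backward
#' filtering). The signal is zero-padded by the filter length so wrap-around
#' cannot leak across the ends; runs in O(N log N) regardless of filter
#' order.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param band length-2 numeric, pass band (Hz)
#' @return filtered signal, same length
#' @export
bandpass <- function(x, fs, band) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  ord <- ceiling(3 * fs / band[1])
  if (ord %% 2 == 1) ord <- ord + 1
  b <- as.numeric(signal::fir1(ord, band * 2 / fs, type = "pass"))
  n <- length(x)
  nfft <- stats::nextn(n + 2 * length(b), 2)
  B <- stats::fft(c(b, numeric(nfft - length(b))))
  X <- stats::fft(c(x, numeric(nfft - n)))
  y <- Re(stats::fft(X * Mod(B)^2, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Instantaneous phase via the analytic signal
#'
#' FFT-based Hilbert transform; phase is 0 deg at the positive peak of the
#' (already band-limited) signal, increasing with time, in [0, 360).
#'
#' @param x band-limited numeric signal
#' @return phase in degrees
#' @export
analytic_phase_deg <- function(x) {
  n0 <- length(x)
  # pad to a highly composite length: R's mixed-radix FFT degrades badly
  # when the length has large prime factors
  n <- stats::nextn(n0, 2)
  x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  z <- stats::fft(X * h, inverse = TRUE) / n
  z <- z[seq_len(n0)]
  (atan2(Im(z), Re(z)) * 180 / pi) %% 360
}

#' Moving RMS amplitude
#'
#' Root-mean-square of the signal in a centred sliding window.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param window_s window length (s), default 0.025
#' @return RMS series, same length (edges padded by shortened windows)
#' @export
moving_rms <- function(x, fs, window_s = 0.025) {
  w <- max(3L, round(window_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  k <- rep(1 / w, w)
  m <- stats::filter(x^2, k, sides = 2)
  m <- as.numeric(m)
  # shrink-to-valid at the edges
  half <- (w - 1L) / 2
  n <- length(x)
  for (i in seq_len(half)) {
    m[i] <- mean(x[1:(i + half)]^2)
    m[n - i + 1] <- mean(x[(n - i + 1 - half):n]^2)
  }
  sqrt(m)
}

#' Welch power spectral density, normalized to unit sum
#'
#' Hanning-windowed 500-ms segments with 50% overlap; segment FFTs are
#' zero-padded to one second so the raw spectral lines fall on a 1 Hz comb,
#' then averaged, truncated to 0-500 Hz (or Nyquist), and normalized so the
#' power sums to 1 across frequency bins.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param window_s segment length (s), default 0.5
#' @param overlap fractional overlap (default 0.5)
#' @param fmax_hz upper frequency bound (default 500)
#' @return data frame: `freq_hz` (bin centres, 1 Hz apart), `power`
#'   (unitless, sums to 1)
#' @export
welch_psd <- function(x, fs, window_s = 0.5, overlap = 0.5, fmax_hz = 500) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("signal shorter than one window")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))  # Hanning
  nfft <- max(nwin, round(fs))          # zero-pad to 1 s -> 1 Hz lines
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)] * win
    acc <- acc + abs(stats::fft(c(seg, numeric(nfft - nwin))))^2
  }
  acc <- acc / length(starts)
  half <- floor(nfft / 2)
  freq <- (0:half) * fs / nfft
  pw <- acc[1:(half + 1)]
  keep <- freq <= min(fmax_hz, fs / 2)
  freq <- freq[keep]; pw <- pw[keep]
  # aggregate onto 1 Hz bins
  bin <- round(freq)
  pb <- tapply(pw, bin, sum)
  out <- data.frame(freq_hz = as.numeric(names(pb)), power = as.numeric(pb))
  out$power <- out$power / sum(out$power)
  out
}

#' Multitaper power spectral density (Thomson's method)
#'
#' Discrete prolate spheroidal (Slepian) tapers are computed from the
#' standard symmetric tridiagonal formulation; for long segments the tapers
#' are computed on a 512-point grid and spline-interpolated, which is
#' accurate for the low-order tapers used here. Eigenspectra are averaged
#' with equal weights.
#'
#' @param x numeric signal segment
#' @param fs sampling rate (Hz)
#' @param nw time-bandwidth product (default 3)
#' @param k number of tapers (default 5)
#' @return data frame: `freq_hz`, `power` (arbitrary units)
#' @export
multitaper_psd <- function(x, fs, nw = 3, k = 5) {
  n <- length(x)
  tapers <- .dpss(n, nw, k)
  acc <- numeric(n)
  for (j in seq_len(k))
    acc <- acc + abs(stats::fft(x * tapers[, j]))^2
  acc <- acc / k
  half <- floor(n / 2)
  data.frame(freq_hz = (0:half) * fs / n, power = acc[1:(half + 1)])
}

# Slepian tapers via the tridiagonal eigenproblem; memoized per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())
.dpss <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  base_n <- if (n > 512) 512L else n
  W <- nw / base_n
  d <- (((base_n - 1) - 2 * (0:(base_n - 1))) / 2)^2 * cos(2 * pi * W)
  e <- (1:(base_n - 1)) * ((base_n - 1):1) / 2
  M <- diag(d)
  M[cbind(1:(base_n - 1), 2:base_n)] <- e
  M[cbind(2:base_n, 1:(base_n - 1))] <- e
  eg <- eigen(M, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  if (n > base_n) {
    V <- apply(V, 2, function(v)
      stats::spline(seq(0, 1, length.out = base_n), v, n = n)$y)
  }
  # normalize and fix sign conventions (symmetric tapers positive mean,
  # antisymmetric positive initial slope)
  V <- apply(V, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (abs(sum(v)) > 1e-8) { if (sum(v) < 0) v <- -v }
    else if (v[2] - v[1] < 0) v <- -v
    v
  })
  .dpss_cache[[key]] <- V
  V
}
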