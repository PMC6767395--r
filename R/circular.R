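#' Circular statistics for spike-phase analysis
#'
#' Angles are handled in degrees at the interface (radians internally). The
#' phase convention throughout the package puts 0 deg at the positive peak of
#' the band-filtered oscillation, increasing with time.
#'
#' @name circular-stats
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Mean resultant vector of a sample of angles
#'
#' The rectangular-coordinate means `X = mean(cos a)`, `Y = mean(sin a)` give
#' the resultant length `r = sqrt(X^2 + Y^2)` (locking strength / phase
#' concentration) and the mean angle `atan2(Y, X)` (preferred phase).
#'
#' @param angles_deg numeric vector of angles in degrees
#' @return list with `angle_deg` in [0, 360), `length` in [0, 1], `n`
#' @export
circ_mean_vector <- function(angles_deg) {
  a <- deg2rad(angles_deg)
  X <- mean(cos(a)); Y <- mean(sin(a))
  r <- sqrt(X^2 + Y^2)
  ang <- rad2deg(atan2(Y, X)) %% 360
  list(angle_deg = ang, length = r, n = length(a))
}

#' Rayleigh test of circular uniformity
#'
#' Tests a sample of angles against the uniform circular distribution; small
#' p indicates significant phase locking. Uses the standard refined
#' approximation for the p value, accurate down to small n.
#'
#' @param angles_deg angles in degrees
#' @return list with `r` (resultant length), `z` (`n * r^2`), `p_value`, `n`
#' @export
rayleigh_test <- function(angles_deg) {
  mv <- circ_mean_vector(angles_deg)
  n <- mv$n
  R <- n * mv$length
  z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(r = mv$length, z = z, p_value = min(1, p), n = n)
}

#' Ratio of modified Bessel functions A(kappa) = I1(kappa)/I0(kappa)
#'
#' The population mean resultant length of a von Mises distribution with
#' concentration `kappa`.
#'
#' @param kappa concentration parameter (>= 0)
#' @export
vm_A <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Inverse of [vm_A]: maximum-likelihood kappa from a resultant length
#'
#' Fisher's piecewise approximation, refined by two Newton steps.
#'
#' @param r mean resultant length in [0, 1)
#' @export
vm_A_inv <- function(r) {
  stopifnot(r >= 0, r < 1)
  if (r < 1e-8) return(0)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  for (i in 1:2) {                      # Newton refinement on A(k) = r
    A <- vm_A(k)
    dA <- 1 - A^2 - A / k
    k <- max(k - (A - r) / dA, 1e-8)
  }
  k
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler.
#'
#' @param n sample size
#' @param mu_deg mean direction (degrees)
#' @param kappa concentration (>= 0); 0 gives the uniform distribution
#' @return angles in degrees in [0, 360)
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 1e-9) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  rad2deg(out) %% 360
}

#' Per-unit spike-phase mean vectors
#'
#' For each unit, the oscillation phases at which its spikes occurred (within
#' the given epochs) are reduced to a mean vector: locking strength (length),
#' preferred phase (angle) and Rayleigh significance.
#'
#' @param spike_times list of numeric spike-time vectors, one per unit
#' @param phase data frame `t`, `phase_deg` (an instantaneous-phase series,
#'   e.g. from [theta_phase])
#' @param epochs interval data frame restricting which spikes count (e.g.
#'   detected theta epochs); `NULL` uses the whole phase series span
#' @param min_spikes units with fewer in-epoch spikes are excluded
#' @return data frame: `unit`, `angle_deg`, `length`, `n_spikes`,
#'   `rayleigh_p`, `significant` (p < 0.05)
#' @export
spike_phase_mean_vector <- function(spike_times, phase, epochs = NULL,
                                    min_spikes = 20) {
  if (is.null(epochs))
    epochs <- iv_new(min(phase$t), max(phase$t))
  # interpolate unwrapped phase so wrap-around does not corrupt interpolation
  unwrapped <- .unwrap_deg(phase$phase_deg)
  rows <- lapply(seq_along(spike_times), function(u) {
    st <- spike_times[[u]]
    st <- st[iv_contains(epochs, st) & st >= min(phase$t) & st <= max(phase$t)]
    if (length(st) < min_spikes) return(NULL)
    ph <- stats::approx(phase$t, unwrapped, xout = st)$y %% 360
    mv <- circ_mean_vector(ph)
    rt <- rayleigh_test(ph)
    data.frame(unit = u, angle_deg = mv$angle_deg, length = mv$length,
               n_spikes = length(st), rayleigh_p = rt$p_value,
               significant = rt$p_value < 0.05)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit = integer(0), angle_deg = numeric(0),
                      length = numeric(0), n_spikes = integer(0),
                      rayleigh_p = numeric(0), significant = logical(0))
  out
}

.unwrap_deg <- function(phase_deg) {
  d <- diff(phase_deg)
  jump <- ifelse(d < -180, 360, ifelse(d > 180, -360, 0))
  phase_deg + c(0, cumsum(jump))
}

#' Population mean phase-locking strength
#'
#' Arithmetic mean of per-unit mean-vector lengths (all units by default, the
#' population summary used for group comparisons; restrict to significantly
#' locked units with `significant_only`).
#'
#' @param mean_vectors data frame from [spike_phase_mean_vector]
#' @param significant_only if TRUE average only Rayleigh-significant units
#' @export
population_locking_strength <- function(mean_vectors, significant_only = FALSE) {
  mv <- mean_vectors
  if (significant_only) mv <- mv[mv$significant, , drop = FALSE]
  mean(mv$length)
}

#' Concentration of preferred phases across units
#'
#' The preferred phases of significantly locked units are reduced to their
#' resultant length `r` (concentration) via rectangular-coordinate means and
#' the angular variance `S2 = 1 - r`. Treating `(n-1) S2` as a chi-square
#' pivot gives the variance-scale confidence interval
#' `[(n-1) S2 / qchisq(1-alpha/2, n-1), (n-1) S2 / qchisq(alpha/2, n-1)]`;
#' its complement `1 - [...]` is the same interval on the concentration
#' scale, which is what error bars on a plotted concentration show.
#'
#' @param mean_vectors data frame from [spike_phase_mean_vector]
#' @param alpha confidence level complement (default 0.05)
#' @param min_units minimum number of significant units required
#' @return list: `r`, `S2`, `ci_lower`, `ci_upper` (angular-variance scale,
#'   bracketing `S2`), `r_ci_lower`, `r_ci_upper` (concentration scale), `n`,
#'   `mean_angle_deg`
#' @export
preferred_phase_concentration <- function(mean_vectors, alpha = 0.05,
                                          min_units = 5) {
  sig <- mean_vectors[mean_vectors$significant, , drop = FALSE]
  n <- nrow(sig)
  if (n < min_units)
    stop("need at least ", min_units, " significantly locked units, got ", n)
  mv <- circ_mean_vector(sig$angle_deg)
  S2 <- 1 - mv$length
  s2_lo <- (n - 1) * S2 / stats::qchisq(1 - alpha / 2, n - 1)
  s2_hi <- (n - 1) * S2 / stats::qchisq(alpha / 2, n - 1)
  list(r = mv$length, S2 = S2,
       ci_lower = s2_lo, ci_upper = min(1, s2_hi),
       r_ci_lower = max(0, 1 - s2_hi), r_ci_upper = min(1, 1 - s2_lo),
       n = n, mean_angle_deg = mv$angle_deg)
}
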