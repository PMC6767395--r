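#' Simulate place-cell spike trains on a trajectory
#'
#' Spikes are drawn from an inhomogeneous Poisson process by Lewis-Shedler
#' thinning. The instantaneous rate of cell c is
#'
#' \deqn{\lambda(t) = b + P \exp(-d(t)^2 / 2\sigma_f^2) \cdot
#'   (1 + \beta (v(t) - \bar v))_+ \cdot \exp(\kappa \cos(\theta(t) -
#'   \phi_{pref})) / I_0(\kappa)}
#'
#' with `b` the baseline rate, `P` the field peak rate, `d(t)` the distance
#' to the field centre, `v(t)` running speed (half-rectified linear gain
#' `beta`), and `theta(t)` the theta phase (von Mises modulation with
#' concentration `kappa`, normalized so the phase factor integrates to 1 over
#' the cycle). The thinning bound is recomputed per cell from the realized
#' speed maximum. An optional multiplicative gain series (assembly / shared
#' slow gain) multiplies the whole rate.
#'
#' @param tracking data frame `t`, `x`, `y` from [generate_trajectory]
#' @param n_cells number of cells
#' @param field_centers optional `n_cells x 2` matrix (cm); default uniform
#'   over a disc of 90% arena radius
#' @param field_sigma_cm place-field width (scalar or per cell)
#' @param peak_rate_hz field peak rate above baseline (scalar or per cell)
#' @param baseline_rate_hz baseline rate (scalar or per cell)
#' @param speed_gain_beta linear speed gain per (cm/s) (scalar or per cell)
#' @param theta_kappa von Mises concentration of theta-phase modulation
#'   (scalar or per cell)
#' @param preferred_phase_deg preferred theta phase per cell; default drawn
#'   uniform
#' @param theta_phase optional data frame `t`, `phase_deg` giving the theta
#'   phase series; required when any `theta_kappa > 0`
#' @param gain optional data frame `t`, `g` (or list of per-cell data
#'   frames) of multiplicative rate gains
#' @param seed optional integer seed (local RNG)
#' @return list with `spike_times` (list of numeric vectors) and
#'   `ground_truth` (data frame of the per-cell parameters)
#' @export
generate_place_cells <- function(tracking, n_cells,
                                 field_centers = NULL,
                                 field_sigma_cm = 10,
                                 peak_rate_hz = 8,
                                 baseline_rate_hz = 0.1,
                                 speed_gain_beta = 0,
                                 theta_kappa = 0,
                                 preferred_phase_deg = NULL,
                                 theta_phase = NULL,
                                 gain = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  rep_n <- function(x) rep_len(x, n_cells)
  sigma <- rep_n(field_sigma_cm); peak <- rep_n(peak_rate_hz)
  base <- rep_n(baseline_rate_hz); beta <- rep_n(speed_gain_beta)
  kappa <- rep_n(theta_kappa)
  ar <- attr(tracking, "arena")
  r_arena <- if (!is.null(ar)) ar$diameter_cm / 2 else 40
  if (is.null(field_centers)) {
    rr <- r_arena * 0.9 * sqrt(stats::runif(n_cells))
    th <- stats::runif(n_cells, 0, 2 * pi)
    field_centers <- cbind(rr * cos(th), rr * sin(th))
  }
  if (is.null(preferred_phase_deg))
    preferred_phase_deg <- stats::runif(n_cells, 0, 360)
  preferred_phase_deg <- rep_n(preferred_phase_deg)
  if (any(kappa > 0) && is.null(theta_phase))
    stop("theta_phase series required when theta_kappa > 0")

  t0 <- tracking$t[1]; t1 <- tracking$t[nrow(tracking)]
  speed <- tracking_speed(tracking)
  vbar <- mean(speed)
  vmax <- max(speed)
  ph_unwrapped <- if (!is.null(theta_phase)) .unwrap_deg(theta_phase$phase_deg)

  spike_times <- vector("list", n_cells)
  for (c_i in seq_len(n_cells)) {
    sfac_max <- max(1 + beta[c_i] * (vmax - vbar), 1, na.rm = TRUE)
    pfac_max <- if (kappa[c_i] > 0)
      exp(kappa[c_i]) / besselI(kappa[c_i], 0) else 1
    gmax <- 1
    gc <- NULL
    if (!is.null(gain)) {
      gc <- if (is.data.frame(gain)) gain else gain[[c_i]]
      gmax <- max(gc$g)
    }
    lmax <- (base[c_i] + peak[c_i] * sfac_max * pfac_max) * gmax
    n_cand <- stats::rpois(1, lmax * (t1 - t0))
    if (n_cand == 0) { spike_times[[c_i]] <- numeric(0); next }
    tc <- sort(stats::runif(n_cand, t0, t1))
    x <- stats::approx(tracking$t, tracking$x, xout = tc)$y
    y <- stats::approx(tracking$t, tracking$y, xout = tc)$y
    v <- stats::approx(tracking$t, speed, xout = tc)$y
    d2 <- (x - field_centers[c_i, 1])^2 + (y - field_centers[c_i, 2])^2
    lam <- peak[c_i] * exp(-d2 / (2 * sigma[c_i]^2)) *
      pmax(1 + beta[c_i] * (v - vbar), 0)
    if (kappa[c_i] > 0) {
      ph <- stats::approx(theta_phase$t, ph_unwrapped, xout = tc)$y
      lam <- lam * exp(kappa[c_i] * cos(deg2rad(ph - preferred_phase_deg[c_i]))) /
        besselI(kappa[c_i], 0)
    }
    lam <- lam + base[c_i]
    if (!is.null(gc)) lam <- lam * stats::approx(gc$t, gc$g, xout = tc, rule = 2)$y
    if (any(lam > lmax + 1e-9)) stop("internal error: thinning bound exceeded")
    keep <- stats::runif(n_cand) < lam / lmax
    spike_times[[c_i]] <- tc[keep]
  }
  gt <- data.frame(cell = seq_len(n_cells),
                   center_x_cm = field_centers[, 1],
                   center_y_cm = field_centers[, 2],
                   field_sigma_cm = sigma, peak_rate_hz = peak,
                   baseline_rate_hz = base, speed_gain = beta,
                   theta_kappa = kappa,
                   preferred_phase_deg = preferred_phase_deg)
  list(spike_times = spike_times, ground_truth = gt)
}

#' Simulate homogeneous Poisson spike trains
#'
#' @param rate_hz rate per cell (recycled)
#' @param n_cells number of cells
#' @param t0,t1 time span (s)
#' @param gain optional shared multiplicative gain data frame `t`, `g`
#'   (thinned against its maximum)
#' @param seed optional seed (local RNG)
#' @return list of spike-time vectors
#' @export
generate_poisson_cells <- function(rate_hz, n_cells, t0, t1, gain = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  rate_hz <- rep_len(rate_hz, n_cells)
  lapply(seq_len(n_cells), function(i) {
    lmax <- rate_hz[i] * (if (is.null(gain)) 1 else max(gain$g))
    n <- stats::rpois(1, lmax * (t1 - t0))
    tc <- sort(stats::runif(n, t0, t1))
    if (!is.null(gain)) {
      g <- stats::approx(gain$t, gain$g, xout = tc, rule = 2)$y
      tc <- tc[stats::runif(n) < rate_hz[i] * g / lmax]
    }
    tc
  })
}
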