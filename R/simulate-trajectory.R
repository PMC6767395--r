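#' Simulate an open-field foraging trajectory
#'
#' Generates head-tracking positions for a rat foraging in a circular arena as
#' an Ornstein-Uhlenbeck velocity random walk, sampled at the tracker's native
#' 25.6 ms interval. Velocity reflects off the arena wall, which preserves the
#' speed distribution near the boundary. An optional two-state mobile/pause
#' process plants immobility periods (velocity exactly zero) with a target
#' time fraction, emulating grooming/rest bouts.
#'
#' Defaults are calibrated so that a 20-min run covers essentially the whole
#' arena when binned at 5 cm (uncovered fraction well under 6%).
#'
#' @param duration_s session duration in seconds (> 0)
#' @param arena_diameter_cm arena diameter (default 80 cm)
#' @param dt_s tracker sampling interval; default 0.0256 s
#' @param tau_s velocity relaxation time of the OU process (s)
#' @param sigma noise amplitude of the OU process (cm s^-3/2); 0 gives a
#'   stationary animal. The stationary mean speed is
#'   `sigma * sqrt(pi * tau_s / 4)`.
#' @param pause_fraction target fraction of time spent immobile in [0, 1).
#'   Pauses are laid out on a 1-s slot grid in multi-second bouts whose total
#'   exactly matches the target fraction, so the planted immobility is
#'   well-defined ground truth.
#' @param pause_mean_s mean pause bout duration (whole seconds, >= 1)
#' @param seed optional integer seed (local RNG; does not disturb the global
#'   RNG stream when supplied)
#' @return data frame `t`, `x`, `y` (s, cm, cm), centred on the arena centre,
#'   with attributes `arena` (list: shape, diameter_cm) and `dt_s`.
#' @export
generate_trajectory <- function(duration_s,
                                arena_diameter_cm = 80,
                                dt_s = 0.0256,
                                tau_s = 0.7,
                                sigma = 22,
                                pause_fraction = 0.1,
                                pause_mean_s = 4,
                                seed = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be a positive number")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  r_wall <- arena_diameter_cm / 2
  n <- floor(duration_s / dt_s) + 1L
  t <- (seq_len(n) - 1L) * dt_s

  # mobile/pause process on a 1-s slot grid with an exact planted pause count
  mobile <- rep(TRUE, n)
  n_slots <- floor(duration_s)
  k <- round(pause_fraction * n_slots)
  if (k > 0) {
    pause_slots <- .plant_pause_slots(n_slots, k, pause_mean_s)
    slot <- pmin(floor(t) + 1L, n_slots)
    mobile[pause_slots[slot]] <- FALSE
  }

  x <- numeric(n); y <- numeric(n)
  vx <- 0; vy <- 0
  a <- exp(-dt_s / tau_s)                      # exact OU decay
  s_eq <- sigma * sqrt(tau_s / 2 * (1 - a^2))  # per-step innovation sd
  ex <- stats::rnorm(n) * s_eq
  ey <- stats::rnorm(n) * s_eq
  px <- 0; py <- 0
  for (i in 2:n) {
    if (mobile[i]) {
      vx <- a * vx + ex[i]
      vy <- a * vy + ey[i]
    } else {
      vx <- 0; vy <- 0
    }
    nx <- px + vx * dt_s
    ny <- py + vy * dt_s
    r2 <- nx * nx + ny * ny
    if (r2 > r_wall^2) {
      # reflect velocity about the wall tangent at the current position
      r <- sqrt(px * px + py * py)
      if (r < 1e-9) { ux <- 1; uy <- 0 } else { ux <- px / r; uy <- py / r }
      vn <- vx * ux + vy * uy
      vx <- vx - 2 * vn * ux
      vy <- vy - 2 * vn * uy
      nx <- px + vx * dt_s
      ny <- py + vy * dt_s
      # if still outside (corner case), clamp to the wall
      r2 <- nx * nx + ny * ny
      if (r2 > r_wall^2) {
        f <- r_wall / sqrt(r2)
        nx <- nx * f; ny <- ny * f
      }
    }
    px <- nx; py <- ny
    x[i] <- px; y[i] <- py
  }
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "arena") <- list(shape = "circle", diameter_cm = arena_diameter_cm)
  attr(out, "dt_s") <- dt_s
  out
}

# Arrange k pause slots among n 1-s slots as separated multi-second bouts.
# Returns a logical vector of length n (TRUE = pause slot).
.plant_pause_slots <- function(n, k, mean_len) {
  mean_len <- max(1, round(mean_len))
  # draw bout lengths until they sum to k
  lens <- integer(0)
  while (sum(lens) < k)
    lens <- c(lens, 1L + stats::rpois(1, mean_len - 1))
  excess <- sum(lens) - k
  lens[length(lens)] <- lens[length(lens)] - excess
  lens <- lens[lens > 0]
  m <- length(lens)
  free <- n - k                       # mobile slots to distribute around bouts
  if (free < m - 1) stop("pause_fraction too high for separated bouts")
  # compose mobile slots into m+1 gaps, internal gaps >= 1
  inner <- m - 1
  extra <- as.vector(stats::rmultinom(1, free - inner, rep(1, m + 1)))
  gaps <- extra + c(0L, rep(1L, inner), 0L)
  out <- logical(n)
  pos <- 0L
  for (i in seq_len(m)) {
    pos <- pos + gaps[i]
    out[(pos + 1L):(pos + lens[i])] <- TRUE
    pos <- pos + lens[i]
  }
  out
}

#' Instantaneous speed at tracking samples
#'
#' Per-sample displacement divided by the sampling interval, lightly smoothed
#' with a centred moving average (default 10 samples, i.e. 256 ms) so the
#' series is usable as a modulation signal. The first sample repeats the
#' second.
#'
#' @param tracking data frame `t`, `x`, `y`
#' @param smooth_samples moving-average half-window support (samples)
#' @return numeric vector of speeds (cm/s), same length as `tracking`
#' @export
tracking_speed <- function(tracking, smooth_samples = 10) {
  d <- c(0, sqrt(diff(tracking$x)^2 + diff(tracking$y)^2))
  dt <- c(NA, diff(tracking$t))
  v <- d / dt
  v[1] <- v[2]
  if (smooth_samples > 1) {
    k <- rep(1 / smooth_samples, smooth_samples)
    v <- stats::filter(v, k, sides = 2)
    v <- as.numeric(v)
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
  }
  v
}
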