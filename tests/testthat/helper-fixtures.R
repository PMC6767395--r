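# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# 6-min foraging trajectory, no pauses (fast, well covered)
fx_trajectory <- function() {
  fixture("traj360", function() generate_trajectory(360, pause_fraction = 0,
                                                    seed = 101))
}

# 20-min default trajectory (used by coverage / map tests)
fx_trajectory_20min <- function() {
  fixture("traj1200", function() generate_trajectory(1200, seed = 102))
}

# a synthetic tracking table moving at constant speed along +x
fx_constant_tracking <- function(speed_cm_s = 10, duration_s = 30,
                                 dt = 0.0256) {
  t <- seq(0, duration_s, by = dt)
  out <- data.frame(t = t, x = speed_cm_s * t - 40, y = 0)
  attr(out, "arena") <- list(shape = "circle", diameter_cm = 80)
  out
}

# deterministic back-and-forth sweeps through the arena centre: every pass
# through a central field has identical duration
fx_sweep_tracking <- function(n_sweeps = 300, speed_cm_s = 20, dt = 0.0256) {
  half_span <- 30
  one_way <- seq(-half_span, half_span, by = speed_cm_s * dt)
  xs <- rep(c(one_way, rev(one_way)), length.out = n_sweeps * length(one_way))
  t <- seq_along(xs) * dt
  out <- data.frame(t = t, x = xs, y = 0)
  attr(out, "arena") <- list(shape = "circle", diameter_cm = 80)
  out
}

# rate-map object with a planted central field (Gaussian in x, sigma 8 cm)
# over the sweep trajectory: passes through the half-peak region have equal
# duration by construction
fx_central_field_map <- function(tr, n_bins = 70, sigma_cm = 8) {
  edges <- seq(-40, 40, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  bin_of <- function(x) pmin(pmax(findInterval(x, edges,
                                               rightmost.closed = TRUE), 1L),
                             n_bins)
  occ <- matrix(0, n_bins, n_bins)
  tab <- table(factor(bin_of(tr$x), levels = 1:n_bins),
               factor(bin_of(tr$y), levels = 1:n_bins))
  occ <- matrix(as.numeric(tab), n_bins, n_bins) * 0.0256
  visited <- occ > 0
  rate <- matrix(0, n_bins, n_bins)
  for (i in 1:n_bins) rate[i, ] <- exp(-centers[i]^2 / (2 * sigma_cm^2))
  rate[!visited] <- 0
  structure(list(raw_rate = rate, smoothed_rate = rate, occupancy_s = occ,
                 spike_count = rate * 0, visited = visited,
                 bin_edges = edges, bin_centers = centers,
                 bin_cm = diff(edges)[1]),
            class = "rate_map")
}

# brute-force linear-domain Poisson decoder over explicit small instances
brute_force_posterior <- function(counts, lam, tau) {
  # counts: vector over cells; lam: bins x cells rate matrix
  lik <- apply(lam, 1, function(lr)
    prod(stats::dpois(counts, lr * tau)))
  lik / sum(lik)
}
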