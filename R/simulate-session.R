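#' Genotype presets for the session generator
#'
#' Two parameter presets encode the qualitative contrasts between control
#' animals and a DISC1-overexpression-like phenotype: the latter has smaller
#' place fields (hence higher spatial information and better decoding),
#' weaker speed modulation of firing, stronger theta phase locking in the
#' novel environment, a wider spread of preferred phases across the
#' population (larger angular variance), no novelty-induced preferred-phase
#' shift, weaker REM theta locking, and a lower pyramidal firing-rate gain
#' during sharp-wave ripples. The numeric values are generator choices that
#' make each contrast detectable in a short session; they are not
#' measurements.
#'
#' @param label `"control"` or `"tgDISC1like"`
#' @return list of class `genotype_preset`
#' @export
ripple_preset <- function(label = c("control", "tgDISC1like")) {
  label <- match.arg(label)
  p <- switch(label,
    control = list(
      label = "control",
      field_sigma_cm = 11,
      speed_gain_beta = 0.04,
      theta_kappa_familiar = 0.8,
      theta_kappa_novel = 0.8,
      rem_kappa = 1.2,
      preferred_phase_spread_deg = 35,
      novelty_phase_shift_deg = 30,
      assembly_gain_sd = 0.6,
      place_cell_scale = 1,
      swr_rate_gain = 5,
      int_swr_rate_gain = 3,
      peak_rate_hz = 8,
      baseline_rate_hz = 0.15,
      sleep_rate_hz = 1.2),
    tgDISC1like = list(
      label = "tgDISC1like",
      field_sigma_cm = 7,
      speed_gain_beta = 0.01,
      theta_kappa_familiar = 0.8,
      theta_kappa_novel = 1.6,
      rem_kappa = 0.6,
      preferred_phase_spread_deg = 80,
      novelty_phase_shift_deg = 0,
      assembly_gain_sd = 0.25,
      place_cell_scale = 1.6,
      swr_rate_gain = 2.5,
      int_swr_rate_gain = 3,
      peak_rate_hz = 8,
      baseline_rate_hz = 0.15,
      sleep_rate_hz = 1.2))
  structure(p, class = "genotype_preset")
}

#' Simulate a full recording session with known ground truth
#'
#' Assembles a session bundle following the standard behavioural protocol:
#' rest, familiar open-field exploration, sleep/rest, novel open-field
#' exploration, sleep/rest. Generates tracking (foraging during
#' explorations, immobility otherwise), pyramidal and interneuron spike
#' trains (inhomogeneous Poisson: place fields, speed gain, theta phase
#' locking, assembly gains, SWR bursts), and a two-channel LFP (theta +
#' phase-gated gamma during exploration and REM, delta + calibrated SWR
#' transients during NREM).
#'
#' Sleep epochs alternate NREM (60 s) and REM (20 s); SWRs occur as a
#' Poisson process within NREM. Cells belong to assemblies whose shared
#' slow gain during exploration creates noise correlations; during SWRs,
#' per-event loadings reuse the assembly structure with weight
#' `reactivation`, so waking cofiring patterns reappear in sleep.
#'
#' @param preset a [ripple_preset] (or its label)
#' @param n_pyr,n_int numbers of pyramidal cells and interneurons
#' @param epoch_durations_s named durations for `rest_pre`,
#'   `familiar_explore`, `sleep_familiar`, `novel_explore`, `sleep_novel`
#' @param fs LFP sampling rate (Hz)
#' @param swr_rate_hz SWR rate within NREM (events/s)
#' @param reactivation weight in [0, 1] of the assembly structure in SWR
#'   event gains (0 = no reactivation)
#' @param swr_z injected SWR amplitude (SD units, see [generate_lfp])
#' @param assembly_gain_sd log-sd of the shared waking assembly gain; the
#'   preset's value when `NULL`. Control carries more location-independent
#'   shared rate variability than the DISC1-like preset (higher index of
#'   dispersion and noise correlation)
#' @param make_lfp generate the LFP channels (default TRUE); with FALSE the
#'   session carries only the planted theta-phase series (in
#'   `ground_truth$theta_phase`), which is cheaper when only spike-level
#'   analyses are needed
#' @param seed integer seed; the session is reproducible given (preset,
#'   sizes, seed)
#' @return list of class `ca1_session`: `tracking`, `units` (data frame
#'   `unit_id`, `cell_class`), `spike_times`, `lfp`, `epochs`, `states`,
#'   `arena`, `ground_truth`
#' @export
simulate_session <- function(preset = ripple_preset("control"),
                             n_pyr = 40, n_int = 8,
                             epoch_durations_s = c(rest_pre = 600,
                                                   familiar_explore = 1200,
                                                   sleep_familiar = 1200,
                                                   novel_explore = 1200,
                                                   sleep_novel = 1200),
                             fs = 1250, swr_rate_hz = 0.35,
                             reactivation = 0.7, swr_z = 10,
                             assembly_gain_sd = NULL,
                             make_lfp = TRUE,
                             seed = 1) {
  if (is.character(preset)) preset <- ripple_preset(preset)
  if (is.null(assembly_gain_sd)) assembly_gain_sd <- preset$assembly_gain_sd
  # the DISC1-like phenotype yields more pyramidal cells whose spatial
  # firing meets the place-cell criteria (its compact fields are easier to
  # qualify); the preset scales the simulated place-cell population
  n_pyr <- max(2L, round(n_pyr * preset$place_cell_scale))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  labels <- c("rest_pre", "familiar_explore", "sleep_familiar",
              "novel_explore", "sleep_novel")
  dur <- epoch_durations_s[labels]
  ends <- cumsum(dur)
  epochs <- data.frame(label = labels, start = c(0, ends[-5]), end = ends,
                       row.names = NULL)
  t_end <- ends[5]

  # ---- behaviour states -------------------------------------------------
  states <- list(data.frame(label = "rest",
                            start = epochs$start[1], end = epochs$end[1]))
  states <- c(states, list(
    data.frame(label = "explore", start = epochs$start[2], end = epochs$end[2])))
  sleep_states <- function(s, e) {
    cyc <- data.frame(label = character(0), start = numeric(0), end = numeric(0))
    tt <- s
    while (tt < e) {
      n_end <- min(tt + 60, e)
      cyc <- rbind(cyc, data.frame(label = "nrem", start = tt, end = n_end))
      tt <- n_end
      if (tt < e) {
        r_end <- min(tt + 20, e)
        cyc <- rbind(cyc, data.frame(label = "rem", start = tt, end = r_end))
        tt <- r_end
      }
    }
    cyc
  }
  states <- c(states, list(sleep_states(epochs$start[3], epochs$end[3])))
  states <- c(states, list(
    data.frame(label = "explore", start = epochs$start[4], end = epochs$end[4])))
  states <- c(states, list(sleep_states(epochs$start[5], epochs$end[5])))
  states <- do.call(rbind, states)

  # ---- tracking ---------------------------------------------------------
  dt <- 0.0256
  tr_fam <- generate_trajectory(dur[2], dt_s = dt)
  tr_nov <- generate_trajectory(dur[4], dt_s = dt)
  arena <- attr(tr_fam, "arena")
  t_all <- seq(0, t_end, by = dt)
  x <- numeric(length(t_all)); y <- numeric(length(t_all))
  put <- function(x, y, seg, t_off) {
    idx <- which(t_all >= t_off & t_all < t_off + max(seg$t) + dt / 2)
    xi <- stats::approx(seg$t + t_off, seg$x, xout = t_all[idx], rule = 2)$y
    yi <- stats::approx(seg$t + t_off, seg$y, xout = t_all[idx], rule = 2)$y
    x[idx] <- xi; y[idx] <- yi
    list(x = x, y = y)
  }
  res <- put(x, y, tr_fam, epochs$start[2]); x <- res$x; y <- res$y
  res <- put(x, y, tr_nov, epochs$start[4]); x <- res$x; y <- res$y
  # stationary at last exploration position during rest/sleep
  for (k in c(1, 3, 5)) {
    idx <- which(t_all >= epochs$start[k] & t_all < epochs$end[k])
    anchor <- if (k == 1) c(0, 0) else {
      prev <- max(which(t_all < epochs$start[k]))
      c(x[prev], y[prev])
    }
    x[idx] <- anchor[1]; y[idx] <- anchor[2]
  }
  tracking <- data.frame(t = t_all, x = x, y = y)
  attr(tracking, "arena") <- arena
  attr(tracking, "dt_s") <- dt

  # ---- oscillation scaffolding -----------------------------------------
  thp <- generate_theta_phase(0, t_end, fs = if (make_lfp) fs else 250)
  nrem_iv <- states[states$label == "nrem", c("start", "end")]
  swr_times <- .poisson_times_in(nrem_iv, swr_rate_hz, min_gap = 0.4)

  # ---- cell parameters --------------------------------------------------
  n_cells <- n_pyr + n_int
  units <- data.frame(unit_id = seq_len(n_cells),
                      cell_class = c(rep("pyr", n_pyr), rep("int", n_int)))
  pop_phase_fam <- stats::runif(1, 0, 360)
  spread_sd <- preset$preferred_phase_spread_deg
  pref_fam <- (pop_phase_fam + stats::rnorm(n_cells, 0, spread_sd)) %% 360
  pref_nov <- (pref_fam + preset$novelty_phase_shift_deg) %% 360
  assembly <- sample(rep_len(seq_len(max(2, round(n_pyr / 6))), n_pyr))

  # ---- assembly gain series (exploration) ------------------------------
  gain_grid <- seq(0, t_end, by = 0.1)
  n_asm <- max(assembly)
  asm_gain <- vapply(seq_len(n_asm), function(a)
    .ou_log_gain(length(gain_grid), dt = 0.1, tau = 0.5, sd = assembly_gain_sd),
    numeric(length(gain_grid)))

  spike_times <- vector("list", n_cells)
  gt_cells <- vector("list", 2)
  for (ep_i in c(2, 4)) {
    novel <- ep_i == 4
    tr <- if (novel) tr_nov else tr_fam
    tr_off <- tr
    tr_off$t <- tr$t + epochs$start[ep_i]
    attr(tr_off, "arena") <- arena
    kappa <- if (novel) preset$theta_kappa_novel else preset$theta_kappa_familiar
    pref <- if (novel) pref_nov else pref_fam
    gains <- lapply(seq_len(n_cells), function(i) {
      g <- if (i <= n_pyr) asm_gain[, assembly[i]] else rep(1, length(gain_grid))
      data.frame(t = gain_grid, g = g)
    })
    pc <- generate_place_cells(
      tr_off, n_cells,
      field_sigma_cm = c(rep(preset$field_sigma_cm, n_pyr), rep(1e6, n_int)),
      peak_rate_hz = c(rep(preset$peak_rate_hz, n_pyr), rep(12, n_int)),
      baseline_rate_hz = c(rep(preset$baseline_rate_hz, n_pyr), rep(3, n_int)),
      speed_gain_beta = c(rep(preset$speed_gain_beta, n_pyr), rep(0.01, n_int)),
      theta_kappa = kappa,
      preferred_phase_deg = pref,
      theta_phase = thp,
      gain = gains)
    for (i in seq_len(n_cells))
      spike_times[[i]] <- c(spike_times[[i]], pc$spike_times[[i]])
    gt_cells[[if (novel) 2 else 1]] <- pc$ground_truth
  }

  # ---- sleep spiking ----------------------------------------------------
  # SWR events behave like compressed replay of the preceding exploration:
  # each event draws an arena location, and pyramidal cells load onto it by
  # the proximity of their place-field centre (familiar map for the first
  # sleep, novel map for the second). The reactivation knob mixes this
  # place-structured loading with per-cell noise, so waking cofiring (which
  # is field-overlap driven) reappears during SWRs in proportion to it.
  rem_iv <- states[states$label == "rem", c("start", "end")]
  swr_dur <- 0.08
  n_ev <- length(swr_times)
  sigma_replay <- 12
  ev_r <- 0.9 * arena$diameter_cm / 2 * sqrt(stats::runif(n_ev))
  ev_th <- stats::runif(n_ev, 0, 2 * pi)
  ev_x <- ev_r * cos(ev_th); ev_y <- ev_r * sin(ev_th)
  in_second_sleep <- swr_times >= epochs$start[5]
  ev_zl <- matrix(0, n_ev, n_pyr)
  for (e in seq_len(n_ev)) {
    gt <- if (in_second_sleep[e]) gt_cells[[2]] else gt_cells[[1]]
    logL <- -((gt$center_x_cm[seq_len(n_pyr)] - ev_x[e])^2 +
                (gt$center_y_cm[seq_len(n_pyr)] - ev_y[e])^2) /
      (2 * sigma_replay^2)
    ev_zl[e, ] <- (logL - mean(logL)) / max(stats::sd(logL), 1e-9)
  }
  ev_ind <- matrix(stats::rnorm(n_ev * n_cells), n_ev, n_cells)
  for (i in seq_len(n_cells)) {
    pyr_i <- i <= n_pyr
    base <- if (pyr_i) preset$sleep_rate_hz else 8
    gain_swr <- if (pyr_i) preset$swr_rate_gain else preset$int_swr_rate_gain
    kappa_rem <- if (pyr_i) preset$rem_kappa else 0.8
    mix <- if (pyr_i)
      sqrt(reactivation) * ev_zl[, i] +
        sqrt(1 - reactivation) * ev_ind[, i]
    else ev_ind[, i]
    ev_gain <- exp(0.6 * mix - 0.18)
    st_nrem <- .sleep_nrem_spikes(nrem_iv, base, swr_times, swr_dur,
                                  gain_swr * ev_gain)
    # REM: theta-locked baseline firing
    st_rem <- .rem_spikes(rem_iv, base * 1.5, kappa_rem,
                          if (pyr_i) pref_fam[i] else pref_fam[i], thp)
    spike_times[[i]] <- sort(c(spike_times[[i]], st_nrem, st_rem))
  }

  # spikes may fall in the fraction of a sampling interval past the last
  # tracking sample; keep everything inside the tracked span
  t_max <- max(t_all)
  spike_times <- lapply(spike_times, function(st) st[st <= t_max])

  # ---- LFP --------------------------------------------------------------
  lfp <- if (make_lfp)
    generate_lfp(states, theta_phase = thp, fs = fs,
                 swr_times = swr_times, swr_z = swr_z)
  else NULL

  structure(list(
    tracking = tracking, units = units, spike_times = spike_times,
    lfp = lfp, epochs = epochs, states = states, arena = arena,
    ground_truth = list(
      preset = preset, cells_familiar = gt_cells[[1]],
      cells_novel = gt_cells[[2]], swr_times = swr_times,
      swr_duration_s = swr_dur, assembly = assembly,
      preferred_phase_familiar = pref_fam,
      preferred_phase_novel = pref_nov,
      reactivation = reactivation,
      theta_phase = thp)),
    class = "ca1_session")
}

#' @export
print.ca1_session <- function(x, ...) {
  cat(sprintf("ca1 session (%s): %d pyr + %d int, %.0f s, %d SWRs\n",
              x$ground_truth$preset$label,
              sum(x$units$cell_class == "pyr"),
              sum(x$units$cell_class == "int"),
              max(x$epochs$end), length(x$ground_truth$swr_times)))
  print(x$epochs)
  invisible(x)
}

#' Interval of one labelled epoch
#'
#' @param session a `ca1_session`
#' @param label epoch label
#' @return single-row interval data frame
#' @export
session_epoch <- function(session, label) {
  row <- session$epochs[session$epochs$label == label, , drop = FALSE]
  if (nrow(row) == 0) stop("no epoch labelled ", label)
  iv_new(row$start, row$end)
}

# Poisson event times within intervals with a minimum gap.
.poisson_times_in <- function(iv, rate, min_gap = 0) {
  out <- numeric(0)
  for (i in seq_len(nrow(iv))) {
    n <- stats::rpois(1, rate * (iv$end[i] - iv$start[i]))
    tt <- sort(stats::runif(n, iv$start[i] + 0.2, iv$end[i] - 0.2))
    if (min_gap > 0 && length(tt) > 1)
      tt <- tt[c(TRUE, diff(tt) >= min_gap)]
    out <- c(out, tt)
  }
  out
}

# OU process in log space, mean-one gain.
.ou_log_gain <- function(n, dt, tau, sd) {
  a <- exp(-dt / tau)
  z <- stats::filter(stats::rnorm(n) * sd * sqrt(1 - a^2), a,
                     method = "recursive")
  exp(as.numeric(z) - sd^2 / 2)
}

# NREM spikes: homogeneous baseline plus per-event burst gains during SWRs.
.sleep_nrem_spikes <- function(nrem_iv, base, swr_times, swr_dur, ev_gain) {
  out <- numeric(0)
  gmax <- max(c(1, ev_gain))
  for (i in seq_len(nrow(nrem_iv))) {
    span <- nrem_iv$end[i] - nrem_iv$start[i]
    n <- stats::rpois(1, base * gmax * span)
    if (n == 0) next
    tc <- stats::runif(n, nrem_iv$start[i], nrem_iv$end[i])
    lam <- rep(base, n)
    if (length(swr_times)) {
      near <- findInterval(tc, swr_times)
      for (side in 0:1) {
        k <- near + side
        ok <- k >= 1 & k <= length(swr_times)
        hit <- ok & abs(tc - swr_times[pmax(pmin(k, length(swr_times)), 1)]) <= swr_dur / 2
        lam[hit] <- base * ev_gain[k[hit]]
      }
    }
    out <- c(out, tc[stats::runif(n) < lam / (base * gmax)])
  }
  sort(out)
}

# REM spikes: theta-phase-modulated rate.
.rem_spikes <- function(rem_iv, base, kappa, pref_deg, thp) {
  if (nrow(rem_iv) == 0) return(numeric(0))
  out <- numeric(0)
  pmaxfac <- if (kappa > 0) exp(kappa) / besselI(kappa, 0) else 1
  un <- .unwrap_deg(thp$phase_deg)
  for (i in seq_len(nrow(rem_iv))) {
    span <- rem_iv$end[i] - rem_iv$start[i]
    n <- stats::rpois(1, base * pmaxfac * span)
    if (n == 0) next
    tc <- stats::runif(n, rem_iv$start[i], rem_iv$end[i])
    lam <- rep(base, n)
    if (kappa > 0) {
      ph <- stats::approx(thp$t, un, xout = tc, rule = 2)$y
      lam <- base * exp(kappa * cos(deg2rad(ph - pref_deg))) / besselI(kappa, 0)
    }
    out <- c(out, tc[stats::runif(n) < lam / (base * pmaxfac)])
  }
  sort(out)
}
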