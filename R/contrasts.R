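#' Summary metrics of one simulated session
#'
#' Runs the core pipeline on a session and returns the population summaries
#' used for genotype contrasts: place-field size, spatial information and
#' speed-rate correlation (familiar exploration), median Bayesian decoding
#' error (familiar), mean theta phase-locking strength and preferred-phase
#' angular variance (novel exploration), and the peak pyramidal peri-SWR
#' firing rate (sleep epochs).
#'
#' @param session a `ca1_session`
#' @param use_lfp_phase measure spike phases against the filtered-LFP theta
#'   phase (requires a generated LFP); with `FALSE` (default) the planted
#'   theta-phase series is used, which isolates spike-level contrasts from
#'   phase-estimation error
#' @param min_spikes minimum in-epoch spikes for a cell to enter map and
#'   phase summaries
#' @return one-row data frame of the seven metrics
#' @export
session_contrast_metrics <- function(session, use_lfp_phase = FALSE,
                                     min_spikes = 50) {
  fam <- session_epoch(session, "familiar_explore")
  nov <- session_epoch(session, "novel_explore")
  pyr <- which(session$units$cell_class == "pyr")
  st_pyr <- session$spike_times[pyr]

  in_fam <- vapply(st_pyr, function(s) sum(iv_contains(fam, s)), numeric(1))
  use <- which(in_fam >= min_spikes)
  maps <- lapply(st_pyr[use], function(s)
    build_rate_map(session$tracking, s, epoch = fam))
  fsf <- vapply(maps, field_size_fraction, numeric(1))
  info <- vapply(maps, function(m) suppressWarnings(skaggs_information(m)),
                 numeric(1))

  dec <- decode_position(session$tracking, st_pyr[use], epoch = fam,
                         maps = maps)
  derr <- decoding_error_summary(dec)$median_error_cm

  src <- speed_rate_correlation(session$tracking, st_pyr, epoch = fam)

  phase <- if (use_lfp_phase) theta_phase(session$lfp)
           else session$ground_truth$theta_phase[, c("t", "phase_deg")]
  mv_nov <- spike_phase_mean_vector(st_pyr, phase, epochs = nov)
  lock_nov <- population_locking_strength(mv_nov)
  conc <- preferred_phase_concentration(mv_nov)

  swr_ev <- data.frame(t = session$ground_truth$swr_times)
  peri <- peri_swr_rates(st_pyr, swr_ev, n_boot = 50)
  peak_rate <- max(peri$rate_hz)

  data.frame(
    field_size_fraction = mean(fsf, na.rm = TRUE),
    spatial_info_bits = mean(info, na.rm = TRUE),
    decoding_error_cm = derr,
    speed_rate_r = mean(src$r, na.rm = TRUE),
    theta_locking_novel = lock_nov,
    phase_angular_variance = conc$S2,
    peri_swr_peak_hz = peak_rate,
    n_cells_used = length(use))
}

#' Paired control vs tgDISC1-like simulation
#'
#' Simulates one session per preset with the same seed (hence identical
#' trajectories, so neural contrasts are not confounded by behaviour) and
#' returns both metric rows.
#'
#' @param seed integer seed shared by the pair
#' @param ... passed to [simulate_session] (sizes, durations)
#' @return two-row data frame with a `preset` column
#' @export
preset_contrast_pair <- function(seed, ...) {
  rows <- lapply(c("control", "tgDISC1like"), function(lab) {
    s <- simulate_session(ripple_preset(lab), make_lfp = FALSE, seed = seed, ...)
    cbind(preset = lab, session_contrast_metrics(s))
  })
  do.call(rbind, rows)
}
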