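fx_session <- function() {
  fixture("small_session", function()
    simulate_session(ripple_preset("control"), n_pyr = 12, n_int = 3,
                     epoch_durations_s = c(rest_pre = 10,
                                           familiar_explore = 120,
                                           sleep_familiar = 100,
                                           novel_explore = 120,
                                           sleep_novel = 100),
                     make_lfp = FALSE, seed = 121))
}

test_that("session bundles satisfy their structural invariants", {
  s <- fx_session()
  # epochs ordered, non-overlapping, protocol order preserved
  expect_equal(s$epochs$label,
               c("rest_pre", "familiar_explore", "sleep_familiar",
                 "novel_explore", "sleep_novel"))
  expect_true(all(diff(as.vector(rbind(s$epochs$start, s$epochs$end))) >= 0))
  # tracking monotone, spikes within session span
  expect_true(all(diff(s$tracking$t) > 0))
  span <- range(s$tracking$t)
  for (st in s$spike_times)
    expect_true(all(st >= span[1] & st <= span[2]))
  # SWR times inside NREM sleep states
  nrem <- s$states[s$states$label == "nrem", c("start", "end")]
  expect_true(all(iv_contains(nrem, s$ground_truth$swr_times)))
  # field centres inside the arena
  gt <- s$ground_truth$cells_familiar
  expect_true(all(gt$center_x_cm^2 + gt$center_y_cm^2 <= 40^2))
})

test_that("sessions are reproducible under a fixed seed", {
  s1 <- fx_session()
  s2 <- simulate_session(ripple_preset("control"), n_pyr = 12, n_int = 3,
                         epoch_durations_s = c(rest_pre = 10,
                                               familiar_explore = 120,
                                               sleep_familiar = 100,
                                               novel_explore = 120,
                                               sleep_novel = 100),
                         make_lfp = FALSE, seed = 121)
  expect_identical(s1$spike_times, s2$spike_times)
  expect_identical(s1$tracking$x, s2$tracking$x)
})

test_that("empirical spike rates track the planted rate parameters", {
  tr <- fx_trajectory_20min()
  pc <- generate_place_cells(tr, 1, field_centers = matrix(c(0, 0), 1),
                             field_sigma_cm = 1e6, peak_rate_hz = 10,
                             baseline_rate_hz = 0, seed = 122)
  # flat field: realized rate within 5% of the planted 10 Hz
  rate <- length(pc$spike_times[[1]]) / max(tr$t)
  expect_lt(abs(rate - 10) / 10, 0.05)
})

test_that("preset pair contrasts run the expected directions on one draw", {
  p <- fixture("pair", function()
    preset_contrast_pair(5, n_pyr = 18, n_int = 3,
                         epoch_durations_s = c(rest_pre = 10,
                                               familiar_explore = 300,
                                               sleep_familiar = 110,
                                               novel_explore = 200,
                                               sleep_novel = 110)))
  d <- p[p$preset == "tgDISC1like", ]
  c <- p[p$preset == "control", ]
  expect_lt(d$field_size_fraction, c$field_size_fraction)
  expect_gt(d$spatial_info_bits, c$spatial_info_bits)
  expect_gt(d$theta_locking_novel, c$theta_locking_novel)
  expect_gt(d$phase_angular_variance, c$phase_angular_variance)
  expect_lt(d$peri_swr_peak_hz, c$peri_swr_peak_hz)
})

test_that("the reactivation knob controls exploration-to-sleep cofiring similarity", {
  dur <- c(rest_pre = 10, familiar_explore = 240, sleep_familiar = 240,
           novel_explore = 60, sleep_novel = 60)
  measure <- function(rho) {
    s <- simulate_session(ripple_preset("control"), n_pyr = 24, n_int = 3,
                          epoch_durations_s = dur, make_lfp = FALSE,
                          reactivation = rho, seed = 131)
    st <- s$spike_times[s$units$cell_class == "pyr"]
    wake_co <- cofiring(st, session_epoch(s, "familiar_explore"))
    ev <- data.frame(t = s$ground_truth$swr_times)
    ev <- ev[ev$t < s$epochs$end[3], , drop = FALSE]
    reactivation_strength(wake_co, cofiring(st, ev, center_events = TRUE))
  }
  hi <- measure(0.9)
  zero <- measure(0)
  expect_gt(hi$reactivation_r, zero$reactivation_r)
  z <- fisher_z_test(hi$reactivation_r, hi$n_pairs,
                     zero$reactivation_r, zero$n_pairs)
  expect_lt(z$p_value, 0.05)
})

test_that("session bundles round-trip through directory serialization", {
  s <- fx_session()
  dir <- tempfile("bundle")
  write_session_bundle(s, dir)
  s2 <- read_session_bundle(dir)
  expect_equal(s2$tracking$x, s$tracking$x, tolerance = 1e-9)
  expect_equal(lengths(s2$spike_times), lengths(s$spike_times))
  expect_equal(s2$epochs$label, s$epochs$label)
  unlink(dir, recursive = TRUE)
})
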