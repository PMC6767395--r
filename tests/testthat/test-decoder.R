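test_that("log-domain decoder matches brute-force enumeration on small instances", {
  set.seed(31)
  for (rep in 1:5) {
    n_cells <- sample(2:5, 1)
    lam <- matrix(runif(9 * n_cells, 0.01, 20), 9, n_cells)  # 9 bins
    counts <- matrix(rpois(3 * n_cells, 2), 3, n_cells)
    tau <- 0.25
    # log-domain posterior as in the decoder
    ll <- counts %*% t(log(lam * tau)) -
      matrix(rowSums(lam) * tau, nrow(counts), 9, byrow = TRUE) -
      rowSums(lgamma(counts + 1))
    post <- exp(ll - apply(ll, 1, max))
    post <- post / rowSums(post)
    for (w in seq_len(nrow(counts))) {
      bf <- brute_force_posterior(counts[w, ], lam, tau)
      expect_lt(max(abs(post[w, ] - bf)), 1e-9)
    }
  }
})

test_that("a cell active only in one bin pins the posterior there", {
  dt <- 0.0256
  # dwell in two spots; spikes only while in the first
  n <- round(5 / dt)
  tr <- data.frame(t = (0:(2 * n)) * dt,
                   x = c(rep(-20, n), rep(20, n + 1)), y = 0)
  attr(tr, "arena") <- list(shape = "circle", diameter_cm = 80)
  st <- list(seq(0.2, 4.8, by = 0.2))
  dec <- decode_position(tr, st, speed_filter_cm_s = 0, n_bins = 10,
                         smooth_sd_bins = 0)
  w_spk <- dec$windows[dec$windows$n_spikes > 0 & dec$windows$t < 5, ]
  expect_true(all(abs(w_spk$decoded_x - (-20)) < 8))
  # posterior rows always normalized
  expect_lt(max(abs(rowSums(dec$posterior) - 1)), 1e-9)
})

test_that("uniform rate maps decode to an uninformative posterior", {
  tr <- fx_trajectory()
  set.seed(32)
  st <- list(sort(runif(2000, 0, 360)), sort(runif(2000, 0, 360)))
  maps <- lapply(st, function(s) build_rate_map(tr, s, n_bins = 10))
  # flatten rates to their mean over visited bins
  maps <- lapply(maps, function(m) {
    mu <- mean(m$smoothed_rate[m$visited])
    m$smoothed_rate[m$visited] <- mu
    m
  })
  dec <- decode_position(tr, st, maps = maps, n_bins = 10)
  spread <- apply(dec$posterior, 1, max)
  expect_lt(stats::median(spread), 2 / sum(maps[[1]]$visited) * 3)
})

test_that("decoding error summary and its trivial cases", {
  expect_equal(decoding_error_summary(data.frame(error_cm = c(1, 2, 9)))$median_error_cm, 2)
  expect_equal(decoding_error_summary(data.frame(error_cm = rep(0, 5)))$median_error_cm, 0)
  expect_error(decoding_error_summary(data.frame(error_cm = numeric(0))), "no decoded")
})

test_that("planted-field decoding beats chance and improves with cell count", {
  tr <- fx_trajectory()
  pc <- generate_place_cells(tr, 40, field_sigma_cm = 9, peak_rate_hz = 8,
                             baseline_rate_hz = 0.1, seed = 33)
  dec20 <- decode_position(tr, pc$spike_times[1:20])
  dec40 <- decode_position(tr, pc$spike_times)
  e20 <- decoding_error_summary(dec20)$median_error_cm
  e40 <- decoding_error_summary(dec40)$median_error_cm
  expect_lt(e40, e20)
  expect_lt(e40, 10)
  # chance level: mean distance between two uniform points in the arena
  # (~0.9 R = 36 cm); the decoder must beat it by a wide margin
  expect_lt(e40, 36 / 3)
})

test_that("less training data degrades decoding", {
  tr <- fx_trajectory()
  pc <- generate_place_cells(tr, 25, field_sigma_cm = 9, peak_rate_hz = 8,
                             baseline_rate_hz = 0.1, seed = 34)
  short_ep <- iv_new(0, 90)
  maps_short <- lapply(pc$spike_times, function(s)
    build_rate_map(tr, s, epoch = short_ep))
  dec_short <- decode_position(tr, pc$spike_times, maps = maps_short)
  dec_full <- decode_position(tr, pc$spike_times)
  expect_gt(decoding_error_summary(dec_short)$median_error_cm,
            decoding_error_summary(dec_full)$median_error_cm)
})
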