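test_that("peri-SWR rates: conservation, planted gain, flat control", {
  set.seed(111)
  ev <- data.frame(t = seq(5, 300, by = 5))
  # planted 3x burst during +-40 ms around each event on a 1 Hz baseline
  base <- 1
  mk_cell <- function() {
    st <- sort(runif(rpois(1, base * 305), 0, 305))
    extra <- unlist(lapply(ev$t, function(e) {
      n <- rpois(1, 2 * base * 0.08)       # 2x extra -> 3x total
      runif(n, e - 0.04, e + 0.04)
    }))
    sort(c(st, extra))
  }
  cells <- replicate(12, mk_cell(), simplify = FALSE)
  peri <- peri_swr_rates(cells, ev, n_boot = 50)
  centre <- peri$rate_hz[abs(peri$t_rel) < 0.03]
  edge <- peri$rate_hz[abs(peri$t_rel) > 0.2]
  expect_gt(mean(centre), 2.2 * mean(edge))
  expect_lt(abs(mean(edge) - base), 0.3)

  # conservation: sum(rate * bin) * n_events * n_cells = total in-window spikes
  total_rate_spikes <- sum(peri$rate_hz) * 0.01 * nrow(ev) * length(cells)
  direct <- sum(vapply(cells, function(st)
    sum(vapply(ev$t, function(e)
      sum(st >= e - 0.25 & st <= e + 0.25), numeric(1))), numeric(1)))
  expect_equal(total_rate_spikes, direct, tolerance = 0.01)

  # spikes independent of events: no centre elevation beyond bin noise
  flat <- peri_swr_rates(replicate(8, sort(runif(900, 0, 300)),
                                   simplify = FALSE), ev, n_boot = 20)
  f_centre <- mean(flat$rate_hz[abs(flat$t_rel) < 0.05])
  f_edge <- mean(flat$rate_hz[abs(flat$t_rel) > 0.15])
  expect_lt(abs(f_centre - f_edge), 0.5)
  expect_error(peri_swr_rates(cells, data.frame(t = 1:5)), "at least 10")
})

test_that("cofiring: identical cells 1, independent ~0, zero-variance excluded", {
  set.seed(112)
  iv <- iv_new(seq(0, 280, by = 20), seq(10, 290, by = 20))
  a <- sort(runif(800, 0, 290))
  co <- cofiring(list(a, a), iv)
  expect_equal(co$r, 1, tolerance = 1e-12)

  cells <- replicate(6, sort(runif(800, 0, 290)), simplify = FALSE)
  co2 <- cofiring(cells, iv)
  expect_lt(abs(mean(co2$r, na.rm = TRUE)), 0.05)

  co3 <- cofiring(list(a, numeric(0)), iv)
  expect_true(is.na(co3$r))
})

test_that("event-centred cofiring windows pad short events to 100 ms", {
  ev <- data.frame(start = c(1, 2), end = c(1.04, 2.06), t = c(1.02, 2.03))
  st <- list(c(0.98, 1.05, 1.99), c(0.99, 1.06, 2.00))
  co <- cofiring(st, ev, center_events = TRUE, min_spikes = 1)
  # windows are [0.97, 1.07] and [1.98, 2.08]: counts (2,1) and (2,1)
  expect_equal(co$r, 1)
})

test_that("reactivation strength: identity 1, shuffled null, planted assemblies", {
  set.seed(113)
  # assemblies: shared gain during waking windows and sleep events
  n_cells <- 12
  asm <- rep(1:3, each = 4)
  wake_iv <- iv_new(0, 200)
  ev <- data.frame(t = seq(205, 400, by = 1.3))
  wake_w <- iv_windows(wake_iv, 0.1)
  g_wake <- matrix(rlnorm(nrow(wake_w) * 3, 0, 0.7), ncol = 3)
  g_ev <- matrix(rlnorm(nrow(ev) * 3, 0, 0.7), ncol = 3)
  cells <- lapply(seq_len(n_cells), function(i) {
    lam_w <- 0.6 * g_wake[, asm[i]]
    spk_w <- unlist(lapply(seq_len(nrow(wake_w)), function(k)
      runif(rpois(1, lam_w[k]), wake_w$start[k], wake_w$end[k])))
    lam_e <- 0.8 * g_ev[, asm[i]]
    spk_e <- unlist(lapply(seq_len(nrow(ev)), function(k)
      runif(rpois(1, lam_e[k]), ev$t[k] - 0.05, ev$t[k] + 0.05)))
    sort(c(spk_w, spk_e))
  })
  wake_co <- cofiring(cells, wake_iv)
  swr_co <- cofiring(cells, ev, center_events = TRUE)
  self <- reactivation_strength(wake_co, wake_co)
  expect_equal(self$reactivation_r, 1)

  res <- reactivation_strength(wake_co, swr_co)
  expect_gt(res$reactivation_r, 0.3)

  # shuffling sleep identities destroys the similarity
  set.seed(114)
  shuf <- swr_co
  shuf$r <- sample(shuf$r)
  null_r <- reactivation_strength(wake_co, shuf)$reactivation_r
  expect_lt(abs(null_r), 2 / sqrt(res$n_pairs) * 2)

  expect_error(reactivation_strength(wake_co[1:4, ], swr_co[1:4, ]), "pairs")
})
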