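test_that("noise correlation: duplicated cell 1, independent cells ~0, shared gain > 0", {
  tr <- fx_trajectory()
  set.seed(41)
  span <- max(tr$t)
  a <- sort(runif(2500, 0, span))
  dup <- noise_correlation(tr, list(a, a))
  expect_equal(dup$r, 1, tolerance = 1e-9)

  cells <- generate_poisson_cells(5, 6, 0, span, seed = 42)
  nc <- noise_correlation(tr, cells)
  expect_lt(abs(mean(nc$r, na.rm = TRUE)), 0.03)

  # shared multiplicative gain induces positive noise correlation
  gg <- seq(0, span, by = 0.25)
  set.seed(43)
  g <- data.frame(t = gg, g = exp(rnorm(length(gg), -0.18, 0.6)))
  gcells <- generate_poisson_cells(6, 4, 0, span, gain = g, seed = 44)
  ncg <- noise_correlation(tr, gcells)
  expect_gt(mean(ncg$r, na.rm = TRUE), 0.05)
})

test_that("partial correlation matches brute-force residual regression", {
  set.seed(45)
  for (i in 1:20) {
    n <- 30
    v <- rnorm(n)
    x <- 0.5 * v + rnorm(n)
    y <- -0.3 * v + rnorm(n)
    rxy <- cor(x, y); rxv <- cor(x, v); ryv <- cor(y, v)
    formula_r <- (rxy - rxv * ryv) / sqrt((1 - rxv^2) * (1 - ryv^2))
    brute <- cor(resid(lm(x ~ v)), resid(lm(y ~ v)))
    expect_lt(abs(formula_r - brute), 1e-12)
  }
})

test_that("speed-compensated correlation removes speed-borne cofiring only", {
  tr <- fx_trajectory()
  # cells coupled only through speed
  pc <- generate_place_cells(tr, 6, field_centers = matrix(0, 6, 2),
                             field_sigma_cm = 1e6, peak_rate_hz = 6,
                             baseline_rate_hz = 0, speed_gain_beta = 0.06,
                             seed = 46)
  nc <- noise_correlation(tr, pc$spike_times)
  sc <- speed_compensated_noise_correlation(tr, pc$spike_times)
  expect_gt(mean(nc$r, na.rm = TRUE), 0.03)
  expect_lt(abs(mean(sc$r, na.rm = TRUE)), 0.03)

  # speed-independent shared gain survives compensation
  span <- max(tr$t)
  gg <- seq(0, span, by = 0.25)
  set.seed(47)
  g <- data.frame(t = gg, g = exp(rnorm(length(gg), -0.18, 0.6)))
  gcells <- generate_poisson_cells(6, 4, 0, span, gain = g, seed = 48)
  scg <- speed_compensated_noise_correlation(tr, gcells)
  expect_gt(mean(scg$r, na.rm = TRUE), 0.05)
})

test_that("matrix is symmetric in cell labels and self-pairs are absent", {
  tr <- fx_trajectory()
  cells <- generate_poisson_cells(5, 4, 0, max(tr$t), seed = 49)
  nc1 <- noise_correlation(tr, cells)
  nc2 <- noise_correlation(tr, rev(cells))
  expect_true(all(nc1$cell_i < nc1$cell_j))
  # relabeling reverses indices but preserves the multiset of correlations
  expect_equal(sort(round(nc1$r, 10)), sort(round(nc2$r, 10)))
})

test_that("stability correlation: identical halves 1, shuffled ~0, group z-test", {
  tr <- fx_trajectory()
  set.seed(50)
  gg <- seq(0, max(tr$t), by = 0.25)
  g <- data.frame(t = gg, g = exp(rnorm(length(gg), -0.18, 0.6)))
  cells <- generate_poisson_cells(8, 8, 0, max(tr$t), gain = g, seed = 51)
  nc <- noise_correlation(tr, cells)
  expect_equal(stability_correlation(nc, nc)$r, 1)

  shuf <- nc
  set.seed(52)
  shuf$r <- sample(shuf$r)
  expect_lt(abs(stability_correlation(nc, shuf)$r), 0.5)

  z <- fisher_z_test(0.8, 100, 0.8, 100)
  expect_equal(z$z, 0)
  expect_equal(z$p_value, 1)
  z2 <- fisher_z_test(0.9, 200, 0.1, 200)
  expect_lt(z2$p_value, 1e-6)
})

test_that("halved epochs partition an exploration", {
  h <- epoch_halves(iv_new(100, 300))
  expect_equal(h$first$end, h$second$start)
  expect_equal(iv_duration(h$first), iv_duration(h$second))
})
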