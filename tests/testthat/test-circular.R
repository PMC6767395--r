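test_that("mean vector length and angle follow closed forms", {
  mv <- circ_mean_vector(rep(90, 50))
  expect_equal(mv$length, 1)
  expect_equal(mv$angle_deg, 90)

  # two angles 0 and 90: r = sqrt(0.5), mean 45
  mv2 <- circ_mean_vector(c(0, 90))
  expect_equal(mv2$length, sqrt(0.5), tolerance = 1e-12)
  expect_equal(mv2$angle_deg, 45)

  # antipodal pair cancels
  expect_lt(circ_mean_vector(c(10, 190))$length, 1e-12)
})

test_that("mean vector is equivariant under global rotation", {
  set.seed(61)
  a <- rvonmises(200, 70, 1.5)
  base <- circ_mean_vector(a)
  rot <- circ_mean_vector((a + 111) %% 360)
  expect_equal(rot$length, base$length, tolerance = 1e-12)
  expect_equal(rot$angle_deg, (base$angle_deg + 111) %% 360, tolerance = 1e-9)
})

test_that("von Mises sampling matches the A(kappa) = I1/I0 length mapping", {
  set.seed(62)
  for (k in c(0.5, 1, 2, 4)) {
    r <- circ_mean_vector(rvonmises(5000, 120, k))$length
    expect_lt(abs(r - vm_A(k)), 0.02)
  }
  # A and its inverse are consistent
  for (r in c(0.1, 0.45, 0.7, 0.9))
    expect_equal(vm_A(vm_A_inv(r)), r, tolerance = 1e-6)
})

test_that("Rayleigh test: uniform null is calibrated, locking is detected", {
  set.seed(63)
  ps <- replicate(500, rayleigh_test(runif(100, 0, 360))$p_value)
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
  expect_lt(rayleigh_test(rvonmises(200, 10, 2))$p_value, 1e-10)
})

test_that("preferred-phase concentration: r, S2 and chi-square interval", {
  mk <- function(angles) data.frame(unit = seq_along(angles),
                                    angle_deg = angles,
                                    length = 0.5, n_spikes = 100,
                                    rayleigh_p = 0.01, significant = TRUE)
  # identical angles: r = 1, S2 = 0
  c1 <- preferred_phase_concentration(mk(rep(33, 8)))
  expect_equal(c1$r, 1)
  expect_equal(c1$S2, 0)

  # angles 0 and 90 replicated: r = sqrt(0.5)
  c2 <- preferred_phase_concentration(mk(rep(c(0, 90), 5)))
  expect_equal(c2$r, sqrt(0.5), tolerance = 1e-12)
  expect_equal(c2$S2, 1 - sqrt(0.5), tolerance = 1e-12)
  # interval brackets the point estimate
  expect_lte(c2$ci_lower, c2$S2)
  expect_gte(c2$ci_upper, c2$S2)
  expect_equal(c2$r_ci_lower, 1 - c2$ci_upper)

  # near-uniform angles: S2 -> 1
  set.seed(64)
  c3 <- preferred_phase_concentration(mk(runif(200, 0, 360)))
  expect_gt(c3$S2, 0.85)

  expect_error(preferred_phase_concentration(mk(c(0, 10))), "at least")
})

test_that("variance-ratio test: F = 1 at equality, calibrated null, detects contrast", {
  eq <- variance_ratio_test(0.4, 50, 0.4, 50)
  expect_equal(eq$F, 1)
  expect_equal(eq$p_value, 1)

  set.seed(65)
  s2 <- function(k, n) 1 - circ_mean_vector(rvonmises(n, 0, k))$length
  ps <- replicate(400, variance_ratio_test(s2(1, 100), 100, s2(1, 100), 100)$p_value)
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)

  pow <- replicate(100, variance_ratio_test(s2(4, 100), 100, s2(0.5, 100), 100)$p_value)
  expect_gt(mean(pow < 0.05), 0.9)

  deg <- variance_ratio_test(0, 50, 0.3, 50)
  expect_equal(deg$flag, "degenerate")
})

test_that("Watson-Williams test: identity null, power at opposite means, shift recovery", {
  set.seed(66)
  a <- rvonmises(60, 100, 2)
  same <- watson_williams_test(a, a)
  expect_gt(same$p_value, 0.99)

  opp <- watson_williams_test(rvonmises(50, 0, 2), rvonmises(50, 180, 2))
  expect_lt(opp$p_value, 0.001)

  # planted 30-degree shift recovered with significance
  sh <- watson_williams_test(rvonmises(200, 90, 2), rvonmises(200, 120, 2))
  expect_lt(abs(sh$shift_deg - 30), 8)
  expect_lt(sh$p_value, 0.01)

  # low-concentration warning flag
  lc <- watson_williams_test(rvonmises(50, 0, 0.3), rvonmises(50, 10, 0.3))
  expect_true(lc$low_concentration)
})
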