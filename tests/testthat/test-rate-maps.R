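test_that("raw rate is spike count over occupancy, conserving total spikes", {
  tr <- fx_trajectory()
  set.seed(7)
  pc <- generate_place_cells(tr, 1, field_centers = matrix(c(5, -10), 1),
                             field_sigma_cm = 10, peak_rate_hz = 8,
                             baseline_rate_hz = 0.1, seed = 7)
  m <- build_rate_map(tr, pc$spike_times[[1]])
  # conservation after the speed filter
  expect_equal(sum(m$raw_rate * m$occupancy_s), sum(m$spike_count))
  expect_true(all(m$occupancy_s >= 0))
  expect_true(all(m$raw_rate[!m$visited] == 0))
})

test_that("a single spike in a visited 1-s bin gives 1 Hz there, 0 elsewhere", {
  dt <- 0.0256
  n <- round(1 / dt)
  # sit in one spot ~1 s, then move fast to another spot
  tr <- data.frame(t = (0:(2 * n)) * dt,
                   x = c(rep(-20, n), seq(-20, 20, length.out = n + 1)),
                   y = 0)
  attr(tr, "arena") <- list(shape = "circle", diameter_cm = 80)
  m <- build_rate_map(tr, spike_times = 0.5, speed_filter_cm_s = 0)
  hit <- which(m$raw_rate > 0, arr.ind = TRUE)
  expect_equal(nrow(hit), 1)
  occ <- m$occupancy_s[hit]
  expect_equal(m$raw_rate[hit], 1 / occ)
  expect_equal(sum(m$spike_count), 1)
})

test_that("Skaggs information matches closed forms and rescaling invariance", {
  # uniform map -> 0 bits/spike
  m <- list(raw_rate = matrix(2, 10, 10), smoothed_rate = matrix(2, 10, 10),
            occupancy_s = matrix(1, 10, 10), visited = matrix(TRUE, 10, 10))
  class(m) <- "rate_map"
  expect_equal(skaggs_information(m), 0)

  # 1 Hz in exactly half the occupancy, 0 elsewhere -> 1 bit/spike
  half <- matrix(0, 10, 10); half[1:5, ] <- 1
  m2 <- m; m2$smoothed_rate <- half; m2$raw_rate <- half
  expect_equal(skaggs_information(m2), 1)

  # information and sparsity invariant under uniform rate rescaling
  m3 <- m2; m3$smoothed_rate <- half * 7.3
  expect_equal(skaggs_information(m3), skaggs_information(m2))
  expect_equal(map_sparsity(m3), map_sparsity(m2))
})

test_that("field size fraction: uniform map 1, single bin 1/visited, analytic Gaussian", {
  m <- list(smoothed_rate = matrix(1, 10, 10), raw_rate = matrix(1, 10, 10),
            occupancy_s = matrix(1, 10, 10), visited = matrix(TRUE, 10, 10))
  class(m) <- "rate_map"
  expect_equal(field_size_fraction(m), 1)

  single <- matrix(0, 10, 10); single[3, 4] <- 5
  m2 <- m; m2$smoothed_rate <- single
  expect_equal(field_size_fraction(m2), 1 / 100)

  # planted Gaussian field: measured fraction ~ pi * (sigma*sqrt(2 ln 10))^2 / arena
  tr <- fx_trajectory_20min()
  pc <- generate_place_cells(tr, 1, field_centers = matrix(c(0, 0), 1),
                             field_sigma_cm = 10, peak_rate_hz = 10,
                             baseline_rate_hz = 0.05, seed = 3)
  mm <- build_rate_map(tr, pc$spike_times[[1]])
  analytic <- pi * (10 * sqrt(2 * log(10)))^2 / (pi * 40^2)
  expect_lt(abs(field_size_fraction(mm) - analytic), 0.05)
})

test_that("sparsity: uniform 1, single active bin equals its occupancy share", {
  m <- list(smoothed_rate = matrix(3, 10, 10), raw_rate = matrix(3, 10, 10),
            occupancy_s = matrix(0.5, 10, 10), visited = matrix(TRUE, 10, 10))
  class(m) <- "rate_map"
  expect_equal(map_sparsity(m), 1)

  # single active bin with occupancy share q -> sparsity q
  occ <- matrix(1, 10, 10); occ[2, 2] <- 25   # q = 25/124
  rate <- matrix(0, 10, 10); rate[2, 2] <- 4
  m2 <- m; m2$occupancy_s <- occ; m2$smoothed_rate <- rate
  q <- 25 / (99 + 25)
  expect_equal(map_sparsity(m2), q)
})

test_that("coherence: planted field smooth, shuffled map ~0, checkerboard negative", {
  tr <- fx_trajectory_20min()
  pc <- generate_place_cells(tr, 1, field_centers = matrix(c(8, 2), 1),
                             field_sigma_cm = 12, peak_rate_hz = 20,
                             baseline_rate_hz = 0.1, seed = 11)
  m <- build_rate_map(tr, pc$spike_times[[1]])
  expect_gt(map_coherence(m), 0.5)

  set.seed(12)
  m_shuf <- m
  v <- m$visited
  m_shuf$raw_rate[v] <- sample(m$raw_rate[v])
  expect_lt(abs(map_coherence(m_shuf)), 0.1)

  chk <- outer(1:10, 1:10, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  m_c <- list(raw_rate = chk, smoothed_rate = chk,
              occupancy_s = matrix(1, 10, 10), visited = matrix(TRUE, 10, 10))
  class(m_c) <- "rate_map"
  expect_lt(map_coherence(m_c), 0)
})

test_that("narrower fields carry more spatial information", {
  tr <- fx_trajectory_20min()
  infos <- vapply(c(8, 14), function(s) {
    pc <- generate_place_cells(tr, 1, field_centers = matrix(c(0, 0), 1),
                               field_sigma_cm = s, peak_rate_hz = 10,
                               baseline_rate_hz = 0.05, seed = s)
    skaggs_information(build_rate_map(tr, pc$spike_times[[1]]))
  }, numeric(1))
  expect_gt(infos[1], infos[2])
})

test_that("remapping score follows its closed form and excludes silent cells", {
  expect_equal(remapping_score(2, 2), 0)
  expect_equal(remapping_score(3, 0), 1)
  expect_equal(remapping_score(3, 1), 0.5)
  expect_true(is.na(remapping_score(0, 0)))
  expect_equal(remapping_score(c(2, 3), c(2, 1)), c(0, 0.5))
})

test_that("smoothed map recovers the planted field centre", {
  tr <- fx_trajectory_20min()
  pc <- generate_place_cells(tr, 1, field_centers = matrix(c(10, -5), 1),
                             field_sigma_cm = 10, peak_rate_hz = 10,
                             baseline_rate_hz = 0.05, seed = 3)
  m <- build_rate_map(tr, pc$spike_times[[1]])
  am <- which(m$smoothed_rate == max(m$smoothed_rate), arr.ind = TRUE)[1, ]
  cx <- m$bin_centers[am[1]]; cy <- m$bin_centers[am[2]]
  expect_lt(sqrt((cx - 10)^2 + (cy + 5)^2), 5)
})
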