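test_that("IQR fences match hand computation and degenerate rules", {
  expect_equal(iqr_fences(c(1, 2, 3, 4, 5), 1.5), c(-1, 7))
  expect_equal(iqr_fences(rep(4.2, 10), 1.5), c(4.2, 4.2))
  expect_equal(iqr_fences(c(1, 2, 3, 4, 5), 0), c(2, 4))
  expect_error(iqr_fences(c(1, 2, 3, NA, NA), 1.5),
               class = "vitalgate_degenerate_window")
})

test_that("IQR fences agree with a brute-force order-statistic oracle", {
  set.seed(21)
  for (i in 1:300) {
    x <- rnorm(sample(5:60, 1), sd = sample(c(0.1, 1, 10), 1))
    k <- runif(1, 0, 3)
    expect_equal(iqr_fences(x, k), oracle_fences(x, k), tolerance = 1e-12)
  }
})

test_that("spike detection flags isolated impulses and nothing on flat input", {
  v <- c(10, 10, 10, 10, 50, 10, 10, 10)
  expect_equal(spike_flags(v), 5L)           # the impulse (1-based index)
  expect_length(spike_flags(rep(3.3, 20)), 0)
  # strictly monotone series equals its rolling median everywhere
  expect_length(spike_flags(1:30 * 2.5), 0)
})

test_that("spike detection agrees with a brute-force oracle on random input", {
  set.seed(31)
  p <- gate_params()
  for (i in 1:300) {
    n <- sample(8:60, 1)
    v <- rnorm(n)
    v[sample(n, sample(0:2, 1))] <- NA           # some missing samples
    v[sample(which(!is.na(v)), 1)] <- 25         # one gross outlier
    expect_equal(spike_flags(v, p), oracle_spikes(v), tolerance = 0)
  }
})

test_that("gate construction combines fences, spikes, missing and expands by delta", {
  # single anomaly mid-window, delta = 2 -> five gated samples, rho = 0.1
  v <- smooth_trend(50)
  v[11] <- 200
  g <- build_gate(v, gate_params())
  expect_true(11 %in% g$anomaly)
  expect_true(all(9:13 %in% g$gate))
  expect_equal(g$rho, length(g$gate) / 50)
  # anomaly at the first sample truncates at the boundary
  v2 <- smooth_trend(50); v2[1] <- 200
  g2 <- build_gate(v2, gate_params())
  expect_equal(g2$gate, 1:3)
  # clean smooth in-range window gates nothing
  g3 <- build_gate(smooth_trend(50), gate_params())
  expect_length(g3$gate, 0)
  expect_equal(g3$rho, 0)
  # all samples missing -> rho = 1
  g4 <- build_gate(rep(NA_real_, 50), gate_params())
  expect_equal(g4$rho, 1)
  # missing samples always gate
  v5 <- smooth_trend(50); v5[20:24] <- NA
  g5 <- build_gate(v5, gate_params())
  expect_true(all(20:24 %in% g5$anomaly))
})

test_that("gates are monotone in kappa and delta", {
  set.seed(41)
  for (i in 1:15) {
    v <- smooth_trend(50) + rnorm(50, sd = 2)
    v[sample(50, 2)] <- c(150, 20)
    v[sample(50, 3)] <- NA
    g_k <- lapply(c(0.5, 1.5, 3), function(k)
      build_gate(v, gate_params(kappa = k))$gate)
    expect_true(all(g_k[[2]] %in% g_k[[1]]))
    expect_true(all(g_k[[3]] %in% g_k[[2]]))
    g_d <- lapply(c(0, 2, 5), function(d)
      build_gate(v, gate_params(delta_samples = d))$gate)
    expect_true(all(g_d[[1]] %in% g_d[[2]]))
    expect_true(all(g_d[[2]] %in% g_d[[3]]))
    expect_true(all(sapply(g_k, length) / 50 <= 1))
  }
})

test_that("clean simulated windows rarely gate (false-gate control)", {
  sim <- simulate_vitals(1000, signals = c("HR", "SPO2", "TEMP"), seed = 6,
                         degradation = no_corruption())
  rho <- unlist(lapply(sim$corrupted, function(s)
    sapply(segment_stream(s, window_plan()), function(w)
      build_gate(w, gate_params())$rho)))
  expect_lte(mean(rho), 0.05)
})
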