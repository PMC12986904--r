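test_that("gap filling splines short gaps exactly and falls back on long ones", {
  p <- restoration_params()
  # linear signal with a 3-sample gap -> exact line values
  v <- 70 + 0.5 * (0:49)
  v[20:22] <- NA
  fg <- fill_gaps(v, p)
  expect_equal(fg$filled, 70 + 0.5 * (0:49), tolerance = 1e-9)
  expect_length(fg$low_confidence, 0)
  # 10-sample gap (> 5 s threshold) -> last-value carry, low confidence
  v2 <- 70 + 0.5 * (0:49)
  v2[20:29] <- NA
  fg2 <- fill_gaps(v2, p)
  expect_equal(fg2$low_confidence, 20:29)
  expect_equal(fg2$filled[20:29], rep(v2[19], 10))
  # untouched valid samples; no gaps -> identity
  expect_equal(fg2$filled[-(20:29)], v2[-(20:29)])
  v3 <- rnorm(50)
  expect_identical(fill_gaps(v3, p)$filled, v3)
  expect_error(fill_gaps(rep(NA_real_, 50), p),
               class = "vitalgate_unrecoverable_window")
})

test_that("EKF converges on constant data and coasts when fully gated", {
  p <- restoration_params()
  b <- hr_bounds
  z <- rep(75, 200)
  out <- ekf_filter(z, integer(0), bounds = b, params = p)
  expect_equal(tail(out$estimates, 1), 75, tolerance = 1e-3)
  expect_equal(out$final_state$x[2], 0, tolerance = 1e-3)
  expect_equal(out$gamma, 0)

  # every index gated with a huge lambda follows pure prediction from init
  init <- vitalgate:::init_ekf_state(80, b, p)
  out2 <- ekf_filter(rep(120, 50), seq_len(50), bounds = b,
                     params = restoration_params(lambda_skip = 1e9),
                     init = init)
  expect_equal(out2$estimates, rep(80, 50), tolerance = 0.05)
  expect_equal(out2$gamma, 1)

  # gamma counts down-weighted indices
  out3 <- ekf_filter(rep(75, 50), 1:10, bounds = b, params = p)
  expect_equal(out3$gamma, 0.2)
  expect_equal(out3$n_full_updates, 40)
  expect_error(ekf_filter(c(1, NA, 3), integer(0), bounds = b, params = p))
})

test_that("EKF innovations are statistically consistent under matched noise", {
  p <- restoration_params()
  b <- hr_bounds
  set.seed(5)
  z <- 80 + rnorm(400, sd = sqrt(p$R_base))
  out <- ekf_filter(z, integer(0), bounds = b, params = p)
  nis <- out$nis[100:400]          # discard transient
  expect_gt(mean(nis, na.rm = TRUE), 0.5)
  expect_lt(mean(nis, na.rm = TRUE), 2)
})

test_that("identity-measurement ablation reduces to a linear KF", {
  p <- restoration_params()
  b <- hr_bounds
  z <- 80 + cumsum(rnorm(100, sd = 0.1))
  out <- ekf_filter(z, integer(0), bounds = b, params = p,
                    measurement = "identity")
  expect_equal(out$estimates[50:100], z[50:100], tolerance = 1)
})

test_that("gated median smoothing only touches gated samples", {
  p <- restoration_params()
  est <- c(1, 2, 100, 3, 4)
  sm <- gated_median_smooth(est, 3L, p)
  expect_equal(sm[3], 3)                        # median of all five
  expect_equal(sm[-3], est[-3])
  expect_identical(gated_median_smooth(est, integer(0), p), est)
  # boundary truncation: k = 1 uses indices 1..3
  sm2 <- gated_median_smooth(c(10, 1, 2, 3, 4), 1L, p)
  expect_equal(sm2[1], 2)
})

test_that("reconstruction merges selectively and errors on uncovered missing", {
  raw <- smooth_trend(50)
  sm <- raw + 1
  g <- build_gate(raw, gate_params())           # empty gate
  rw <- reconstruct_window(raw, sm, g)
  expect_identical(rw$values, raw)              # identity path
  g$gate <- 9:13
  rw2 <- reconstruct_window(raw, sm, g)
  expect_equal(sum(rw2$values != raw), 5)
  g$gate <- seq_len(50)
  expect_identical(reconstruct_window(raw, sm, g)$values, sm)
  raw2 <- raw; raw2[30] <- NA
  expect_error(reconstruct_window(raw2, sm, build_gate(raw, gate_params())))
})

test_that("stream restoration is selective: ungated samples are bit-identical", {
  sim <- simulate_vitals(1000, signals = "HR", seed = 2)
  rs <- restore_stream(sim$corrupted$HR, bounds = sim$bounds)
  for (w in rs$windows) {
    out <- setdiff(seq_len(50), w$gate$gate)
    expect_identical(w$smoothed[out], w$raw[out])
    expect_false(anyNA(w$smoothed))
  }
  # full-weight update count complements the down-weighted fraction
  for (w in rs$windows[1:10])
    expect_equal(w$n_full_updates, round(50 * (1 - w$gamma)))
})

test_that("restoration helps under the strong regime and stages are ordered", {
  sim <- simulate_vitals(1500, signals = c("HR", "SPO2", "TEMP"), seed = 1)
  for (sid in names(sim$corrupted)) {
    rs <- restore_stream(sim$corrupted[[sid]], bounds = sim$bounds)
    cl <- as.numeric(sim$clean[[sid]])
    expect_gte(length(rs$windows), 20)
    m <- sapply(rs$windows, function(w) {
      tr <- cl[w$start_sample:(w$start_sample + 49)]
      st <- vitalgate:::window_stage_series(w)
      vapply(st, function(x) mean((x - tr)^2), numeric(1))
    })
    avg <- rowMeans(m)
    expect_lt(avg["smoothed"], avg["corrupted"])      # restoration helps
    expect_gte(avg["interpolated"], avg["ekf"])       # stage cascade
    expect_gte(avg["ekf"], avg["smoothed"] - 1e-9)
  }
})

test_that("unrecoverable all-missing windows carry state and stay complete", {
  v <- smooth_trend(150)
  v[60:120] <- NA                                    # > one full window missing
  rs <- restore_stream(make_stream(v), bounds = clinical_bounds())
  expect_false(anyNA(as.numeric(rs$stream)))
  recovered <- vapply(rs$windows, `[[`, logical(1), "recovered")
  expect_true(any(!recovered))
})
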