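test_that("the ADF test separates random walks from stationary series", {
  set.seed(8)
  pw <- replicate(20, adf_test(cumsum(rnorm(200)))$p.value)
  ps <- replicate(20, adf_test(arima.sim(list(ar = 0.3), 200))$p.value)
  expect_gt(mean(pw > 0.05), 0.8)     # unit roots: usually fail to reject
  expect_gt(mean(ps < 0.05), 0.8)     # stationary: usually reject
  expect_equal(adf_test(rep(5, 50))$p.value, 0.99)
  expect_error(adf_test(1:5))
})

test_that("order selection applies the near-constant and stationarity fallbacks", {
  cfg <- forecast_config()
  expect_equal(select_order(rep(72.4, 50), cfg, "HR"), c(1L, 0L, 0L))
  # HR-scale random walk, step sd 2: differenced sd >> 0.1 and non-stationary
  set.seed(9)
  rw <- 80 + cumsum(rnorm(50, sd = 2))
  expect_equal(select_order(rw, cfg, "HR"), c(1L, 1L, 1L))
  # differenced sd below the HR threshold of 0.1 -> AR(1) fallback
  slow <- 80 + cumsum(rnorm(50, sd = 0.05))
  expect_lt(sd(diff(slow)), 0.1)
  expect_equal(select_order(slow, cfg, "HR"), c(1L, 0L, 0L))
  expect_error(select_order(rep(1, 5), cfg, "HR"))
})

test_that("near-constant windows always fall back; volatile windows never do", {
  cfg <- forecast_config()
  set.seed(10)
  flat <- replicate(20, {
    o <- select_order(97 + rnorm(50, sd = 0.01), cfg, "SPO2")
    o[2] == 0
  })
  expect_true(all(flat))
  wild <- replicate(20, {
    o <- select_order(80 + cumsum(rnorm(50, sd = 3)), cfg, "HR")
    o[2] == 1
  })
  expect_gt(mean(wild), 0.9)
})

test_that("one-step forecasts respect interval ordering and constant input", {
  cfg <- forecast_config()
  fc <- forecast_one_step(rep(70, 50), cfg, "HR")
  expect_equal(fc$point, 70, tolerance = 1e-6)
  expect_lte(fc$pi_low, fc$point)
  expect_gte(fc$pi_high, fc$point)
  set.seed(12)
  for (i in 1:10) {
    y <- 80 + cumsum(rnorm(60, sd = runif(1, 0.05, 3)))
    fc <- forecast_one_step(y, cfg, "HR")
    expect_lte(fc$pi_low, fc$point)
    expect_gte(fc$pi_high, fc$point)
  }
})

test_that("difference-based forecasts are shift-equivariant", {
  set.seed(13)
  y <- 80 + cumsum(rnorm(80, sd = 1.5))
  cfg <- forecast_config()
  f0 <- forecast_one_step(y, cfg, "HR")
  f7 <- forecast_one_step(y + 7, cfg, "HR")
  expect_equal(f7$point, f0$point + 7, tolerance = 1e-6)
  expect_equal(f7$pi_high - f7$pi_low, f0$pi_high - f0$pi_low,
               tolerance = 1e-6)
})

test_that("prediction intervals achieve near-nominal coverage when well specified", {
  # Monte-Carlo oracle: ARIMA(1,1,1) truth, 1-step 95% intervals
  set.seed(14)
  cfg <- forecast_config(history_len = 500)
  hits <- replicate(60, {
    y <- as.numeric(arima.sim(list(ar = 0.5, ma = 0.3), n = 501))
    y <- cumsum(y)
    fc <- forecast_one_step(y[1:500], cfg, "HR", horizon = 1)
    y[501] >= fc$pi_low && y[501] <= fc$pi_high
  })
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 1.0)
})

test_that("forecast falls back to a naive interval when fitting is impossible", {
  cfg <- forecast_config()
  # constant with a single step: CSS-ML may fit, but the naive path is exercised
  # directly through the internal chain on a degenerate two-level series
  y <- c(rep(1, 49), 2)
  fc <- forecast_one_step(y, cfg, "HR")
  expect_true(is.finite(fc$point))
  expect_lte(fc$pi_low, fc$point)
})
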