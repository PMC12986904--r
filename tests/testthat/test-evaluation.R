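test_that("stage gains reproduce the reference table arithmetic", {
  # HR: interpolated 2345.18 -> EKF 1237.66 is a 47.2% gain
  expect_equal(round(stage_gain(2345.18, 1237.66), 1), 47.2)
  # systolic BP corrupted 4979.33 -> smoothed 2331.84: 53.2% cumulative
  expect_equal(round(stage_gain(4979.33, 2331.84), 1), 53.2)
  # glucose corrupted 4910.27 -> smoothed 1634.67: 66.7% cumulative
  expect_equal(round(stage_gain(4910.27, 1634.67), 1), 66.7)
  expect_equal(stage_gain(3, 3), 0)
  expect_error(stage_gain(0, 1))
})

test_that("range-normalized errors scale by the corrupted window range", {
  truth <- smooth_trend(50)
  expect_equal(unname(normalized_errors(truth, truth, truth)), c(0, 0))
  corr <- c(60, 100, truth[-(1:2)])          # range exactly 40
  est <- truth + 4                           # 0.1 after scaling by 40
  ne <- normalized_errors(est, truth, corr)
  expect_equal(unname(ne["MAE"]), 0.1)
  expect_equal(unname(ne["RMSE"]), 0.1)
  # affine transforms of all three series leave the result unchanged
  ne2 <- normalized_errors(3 * est + 5, 3 * truth + 5, 3 * corr + 5)
  expect_equal(ne2, ne, tolerance = 1e-12)
  expect_error(normalized_errors(truth, truth, rep(1, 50)),
               class = "vitalgate_zero_range")
})

test_that("forecast metrics behave at the perfect and adversarial limits", {
  actual <- c(82, 79, 85, 78)
  last <- c(80, 80, 80, 80)
  perfect <- data.frame(point = actual, pi_low = actual - 1,
                        pi_high = actual + 1)
  fm <- forecast_metrics(perfect, actual, last)
  expect_equal(unname(fm["window_MAE"]), 0)
  expect_equal(unname(fm["directional_accuracy"]), 1)
  expect_equal(unname(fm["pi_coverage"]), 1)
  expect_equal(unname(fm["slope_error"]), 0)
  opposite <- data.frame(point = 2 * last - actual,
                         pi_low = -1e6, pi_high = 1e6)
  fm2 <- forecast_metrics(opposite, actual, last)
  expect_equal(unname(fm2["directional_accuracy"]), 0)
  expect_error(forecast_metrics(perfect[0, ], numeric(0), numeric(0)))
})

test_that("confusion metrics reproduce the reference operating points", {
  # respiratory rate row: TPR 1.000 / TNR 0.703
  m <- confusion_metrics(list(TP = 1000, FN = 0, TN = 703, FP = 297))
  expect_equal(unname(m["balanced_accuracy"]), 0.852, tolerance = 6e-4)
  expect_equal(round(unname(m["youden_j"]), 3), 0.703)
  expect_equal(round(unname(m["FPR"]), 3), 0.297)
  # aggregated multi-modal operating point: TPR 0.89 / TNR 0.92
  m2 <- confusion_metrics(list(TP = 89, FN = 11, TN = 92, FP = 8))
  expect_equal(round(unname(m2["balanced_accuracy"]), 3), 0.905)
  expect_equal(round(unname(m2["youden_j"]), 2), 0.81)
  m3 <- confusion_metrics(list(TP = 10, FN = 0, TN = 10, FP = 0))
  expect_equal(unname(m3[c("TPR", "TNR", "FPR", "FNR")]), c(1, 1, 0, 0))
  expect_true(is.na(confusion_metrics(list(TP = 0, FN = 0, TN = 5, FP = 5))["TPR"]))
})

test_that("confusion metrics agree with brute-force recounts", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    truth <- rbinom(n, 1, runif(1, 0.1, 0.9))
    risk <- runif(n)
    tau <- runif(1)
    cc <- classify_and_count(risk, tau, truth)
    pred <- risk >= tau
    expect_equal(cc$TP, sum(pred & truth == 1))
    expect_equal(cc$TN, sum(!pred & truth == 0))
    m <- confusion_metrics(cc)
    if (any(truth == 1))
      expect_equal(unname(m["TPR"]), sum(pred & truth == 1) / sum(truth == 1))
    if (any(truth == 0))
      expect_equal(unname(m["TNR"]), sum(!pred & truth == 0) / sum(truth == 0))
  }
})

test_that("lead times match alerts to subsequent events within the horizon", {
  lt <- lead_times(100, 125)
  expect_equal(lt$leads, 25)
  expect_equal(lt$mean, 25)
  # no alert before the event -> missed
  lt2 <- lead_times(numeric(0), 125)
  expect_equal(lt2$n_missed, 1)
  expect_true(is.na(lt2$mean))
  # alert only after the event counts as missed too
  lt3 <- lead_times(130, 125)
  expect_equal(lt3$n_missed, 1)
  # outside the matching horizon
  lt4 <- lead_times(0, 125, horizon_s = 120)
  expect_equal(lt4$n_missed, 1)
})

test_that("paired stage tests subsample consistently and detect improvement", {
  set.seed(18)
  a <- rexp(2000, 1 / 10)
  expect_equal(unname(paired_stage_tests(a, a, 997, seed = 3)),
               c(1, 1))
  b <- a - 5
  p <- paired_stage_tests(a, b, 997, seed = 3)
  expect_lt(p["p_t"], 0.001)
  expect_lt(p["p_wilcoxon"], 0.001)
  # same seeded subsample -> reproducible p-values
  bb <- a + rep(c(-1, 1), 1000)
  expect_identical(paired_stage_tests(a, bb, 997, seed = 3),
                   paired_stage_tests(a, bb, 997, seed = 3))
  expect_error(paired_stage_tests(a[1:10], b[1:10], 997))
})

test_that("savings factor is the complement of the gating rate", {
  expect_equal(savings_factor(0.214), 78.6)
  expect_equal(savings_factor(0), 100)
  expect_equal(savings_factor(1), 0)
  expect_error(savings_factor(1.2))
})
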