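test_that("clean streams are seed-deterministic, in range, and right length", {
  cfg <- trend_config("HR", 3600, seed = 7)
  s1 <- generate_clean_stream(cfg)
  s2 <- generate_clean_stream(cfg)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_length(s1, 3600)
  expect_gte(min(s1), 60)
  expect_lte(max(s1), 100)
  expect_false(anyNA(s1))
  # a different seed gives a different trajectory
  cfg2 <- trend_config("HR", 3600, seed = 8)
  expect_false(identical(as.numeric(s1),
                         as.numeric(generate_clean_stream(cfg2))))
  expect_error(generate_clean_stream(trend_config("XYZ", 100)))
})

test_that("coarse records resample through a natural spline exactly at knots", {
  # knots on a straight line -> resampled values on that line
  kt <- seq(0, 3000, by = 600)
  line <- 70 + 0.01 * kt
  st <- resample_coarse_to_stream(data.frame(time_s = kt, value = line), 1)
  expect_equal(as.numeric(st), 70 + 0.01 * (0:3000), tolerance = 1e-9)
  # 600x densification between consecutive knots
  expect_length(st, 3001)
  # knot values reproduced exactly on a curved record
  set.seed(2)
  vals <- 80 + cumsum(rnorm(6))
  st2 <- resample_coarse_to_stream(data.frame(time_s = kt, value = vals), 1)
  expect_equal(as.numeric(st2)[kt + 1], vals, tolerance = 1e-12)
  expect_error(resample_coarse_to_stream(
    data.frame(time_s = c(0, 0, 600), value = 1:3), 1))
})

test_that("degradation injection respects quantization, missing fraction, masks", {
  clean <- generate_clean_stream(trend_config("HR", 1000, seed = 3))
  cfg <- degradation_config(seed = 5)
  out <- inject_degradation(clean, cfg, 50)
  v <- as.numeric(out$stream)

  # observed values are integer multiples of the 0.2 quantization step
  obs <- v[!is.na(v)]
  expect_true(all(abs(obs / 0.2 - round(obs / 0.2)) < 1e-8))

  # per-window missing fraction within the configured [0.20, 0.30]
  fr <- sapply(seq(1, 1000, by = 50), function(s) mean(is.na(v[s:(s + 49)])))
  expect_true(all(fr >= 0.20 - 1e-9 & fr <= 0.30 + 1e-9))

  # mask fidelity: missing flag <-> NA
  expect_identical(which(is.na(v)), which(out$mask[, "missing"]))
  expect_identical(dim(out$mask), c(1000L, 6L))

  # determinism
  out2 <- inject_degradation(clean, cfg, 50)
  expect_identical(as.numeric(out2$stream), v)
  expect_identical(out2$mask, out$mask)

  expect_error(inject_degradation(clean, cfg, 2000))
  expect_error(inject_degradation(out$stream, cfg, 50))  # wrong provenance
})

test_that("zero-magnitude degradation is a no-op up to quantization", {
  clean <- generate_clean_stream(trend_config("HR", 600, seed = 3))
  cfg <- no_corruption()
  out <- inject_degradation(clean, cfg, 50)
  expect_identical(as.numeric(out$stream), as.numeric(clean))
  # with quantization back on, the only difference is the rounding
  cfgq <- no_corruption(); cfgq$quantization_step <- 0.2
  outq <- inject_degradation(clean, cfgq, 50)
  expect_equal(as.numeric(outq$stream), as.numeric(clean), tolerance = 0.1001)
})

test_that("spike counts are monotone in spike probability; values stay bounded", {
  clean <- generate_clean_stream(trend_config("HR", 1000, seed = 3))
  counts <- sapply(c(0.01, 0.05, 0.15), function(p) {
    cfg <- degradation_config(spike_probability = p, seed = 9)
    sum(inject_degradation(clean, cfg, 50)$mask[, "spike"])
  })
  expect_true(all(diff(counts) >= 0))
  # soft-clip containment: observed corrupted values within the clinical
  # saturation limits (up to half a quantization step)
  out <- inject_degradation(clean, degradation_config(seed = 2), 50)
  obs <- as.numeric(out$stream); obs <- obs[!is.na(obs)]
  expect_gte(min(obs), 60 - 0.1000001)
  expect_lte(max(obs), 100 + 0.1000001)
})

test_that("simulate_vitals produces paired streams for every signal", {
  sim <- simulate_vitals(600, signals = c("HR", "SPO2"), seed = 4)
  expect_named(sim$clean, c("HR", "SPO2"))
  expect_named(sim$corrupted, c("HR", "SPO2"))
  expect_length(sim$clean$HR, 600)
  expect_false(anyNA(sim$clean$SPO2))
  expect_true(anyNA(sim$corrupted$SPO2))
  sim2 <- simulate_vitals(600, signals = c("HR", "SPO2"), seed = 4)
  expect_identical(as.numeric(sim2$corrupted$HR), as.numeric(sim$corrupted$HR))
})
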