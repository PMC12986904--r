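# vitalgate

Selective ("gated") restoration and early warning for corrupted streaming
vital signs.

Wearable body-sensor networks deliver 1 Hz trend-level vitals — heart rate,
SpO2, blood pressures, respiratory rate, temperature, glucose — degraded by
burst packet loss, sensor noise, motion-artifact spikes, baseline wander,
drift, soft saturation and coarse quantization. Conventional pipelines
reprocess every sample, wasting computation and distorting clean
physiology. `vitalgate` instead detects corrupted samples per sliding
window and restores *only those*, passing everything else through
bit-identical, then forecasts each signal one stride ahead and converts
forecasts into clipped clinical risk scores and alerts.

For each 50-s window (10-s stride, 80% overlap) of each signal *j* with
clinical range [L, U]:

1. **Gating.** Anomaly set A = {out of IQR fences [Q1 − κ·IQR, Q3 + κ·IQR]}
   ∪ {spikes: |z − rolling median| > η·MAD} ∪ {missing}; gate set
   G = A dilated by δ samples; gating rate ρ = |G|/N. Defaults κ = 1.5,
   δ = 2, η = 3. Expected computational savings ≈ 100·(1 − ρ) %.
2. **Restoration.** Gaps ≤ 5 s are filled with a natural cubic spline
   (longer gaps: last value, flagged low-confidence); a two-state
   (level, slope) extended Kalman filter with the bounded logistic sensor
   model h(s) = L + (U − L)·σ((s − b)/a), b = (L+U)/2, a = (U−L)/(2 ln 19)
   (so the bounds sit at the 5%/95% saturation levels) filters the window,
   inflating measurement noise by λ = 10³ on gated indices; a local median
   over ±2 samples smooths gated estimates; finally restored values replace
   only the gated samples.
3. **Forecasting.** ARIMA(1,1,1) refit per window (maximum likelihood, 50
   samples) with fallback to AR(1) on near-constant or already-stationary
   windows (differenced-sd threshold + augmented Dickey–Fuller test); one
   point forecast 10 s ahead with a 95% prediction interval.
4. **Risk.** Z = α·|ŷ − μ|/σ + (1 − α)·min(|ŷ − C|/R, 1) with α = 0.1,
   C = (L+U)/2, R = (U−L)/2; clipped risk r = min(Z, 1); the aggregate risk
   is the mean of r across signals; alerts fire at per-signal thresholds
   and at 0.35 for the aggregate.

A seeded synthetic-data module generates paired clean/corrupted streams
under a strong degradation regime (20–30% burst missingness, noise sd 8% of
the clinical range, ±4σ spikes at 5%, half-cycle wander, accumulating
drift, soft clipping, 0.2-unit quantization), and an evaluation module
computes stage-wise MSE gains, range-normalized errors, forecast
calibration, pooled confusion metrics, lead times and paired stage tests.

## Worked example

```r
library(vitalgate)

sim <- simulate_vitals(1200, signals = c("HR", "SPO2", "SYS"), seed = 7)
fit <- vitalgate(sim)          # gate -> restore -> forecast -> risk
summary(fit)
```

```
vitalgate fit: 3 signals, 116 windows each (T=50s, S=10s)
  gating rate rho_avg = 0.781 (savings ~ 21.9%)
  cumulative MSE reduction (mean) = 2.8%

Stage MSE vs ground truth (per signal):
 signal mse_corrupted mse_interpolated mse_ekf mse_smoothed ekf_gain_pct
     HR       19.0403          25.8612 20.3889      20.2564        21.16
   SPO2        0.3357           0.5117  0.3471       0.3434        32.17
    SYS        6.3470           8.1454  5.2941       5.2664        35.01
 ...
Forecasting (one stride ahead):
 signal window_MAE directional_accuracy slope_error pi_coverage risk_error
     HR     3.2209               0.6696     0.32209      0.8522     0.1385
   SPO2     0.4256               0.6957     0.04256      0.7739     0.1435
    SYS     1.6387               0.6696     0.16387      0.6522     0.0999

Global event detection (aggregated risk):
              TPR               TNR               FPR               FNR
            1.000             0.132             0.868             0.000
Lead time: mean 8.0 s, median 8.0 s (0 missed)
```

Reading this: roughly 78% of samples were gated under the strong regime
(mostly missingness dilation and spike shoulders), the EKF stage cuts the
interpolated-stage error by 21–35% per signal, forecasts land within the
95% interval 65–86% of the time at a 10-s horizon, and every true
bound-contact event was alerted ~8 s in advance, at the price of a high
false-alarm rate — the aggregate threshold is deliberately sensitive.

```r
predict(fit)     # next-stride forecasts from the end of each stream
#   signal  point pi_low pi_high order
# 1     HR  72.14  61.38    82.9 1,1,1
# 2   SPO2  98.62  95.90   101.4 1,1,1
# 3    SYS 101.88  98.66   105.1 1,1,1
plot(fit, "HR", xlim = c(0, 300))   # clean / corrupted / restored overlay
```

A command-line front end over the same functions lives in
`inst/cli/vitalgate.R` (verbs `simulate`, `restore`, `forecast`, `risk`,
`run`, `evaluate`, `config`).

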