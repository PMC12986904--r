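Package: vitalgate
Title: Selective Gated Restoration and Early Warning for Streaming Vital Signs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for restoring corrupted wearable-sensor (WBAN) vital-sign
    streams and turning them into clinical early warnings. Streams are
    segmented into overlapping sliding windows; statistically corrupted
    samples are detected per window (IQR fences, rolling-median/MAD spike
    test, missingness) and only those samples are restored, via natural
    cubic-spline gap filling, an extended Kalman filter with a bounded
    logistic sensor model, and gated local median smoothing. Clean samples
    pass through untouched. Restored windows feed an adaptive ARIMA(1,1,1)
    one-step forecaster with prediction intervals, and forecasts are mapped
    to clipped, clinically-aware risk scores and event alerts. Includes a
    synthetic generator for trend-level vitals with a configurable strong
    degradation model (burst missingness, noise, wander, spikes, drift,
    soft clipping, quantization) and a full evaluation suite (stage-wise
    MSE gains, normalized errors, forecast calibration, confusion metrics,
    lead times, paired stage tests).
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Encoding: UTF-8
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
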