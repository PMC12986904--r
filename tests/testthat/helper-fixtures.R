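# shared fixtures: small streams and brute-force oracles used across files

hr_bounds <- clinical_bounds("HR")

make_stream <- function(values, sid = "HR", provenance = "corrupted") {
  signal_stream(values, sid, 1, 0, provenance)
}

# a smooth in-range HR-like trend of length n (deterministic)
smooth_trend <- function(n, baseline = 80, amp = 5, period = 400) {
  baseline + amp * sin(2 * pi * (seq_len(n) - 1) / period)
}

# zero-corruption degradation config (everything off)
no_corruption <- function(seed = 1) {
  degradation_config(missing_fraction_range = c(0, 0),
                     noise_sd_fraction_of_range = 0,
                     wander_amplitude_sd_fraction = 0,
                     spike_probability = 0,
                     drift_sd_fraction_per_window = 0,
                     quantization_step = 0, soft_clip = FALSE, seed = seed)
}

# brute-force quartiles by linear interpolation of order statistics (type 7),
# written independently of stats::quantile
oracle_quartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_fences <- function(x, kappa) {
  q1 <- oracle_quartile(x, 0.25); q3 <- oracle_quartile(x, 0.75)
  c(q1 - kappa * (q3 - q1), q3 + kappa * (q3 - q1))
}

# brute-force rolling-median / MAD spike detector mirroring the definition
# (truncated neighbourhoods, valid samples only, window-level MAD about m)
oracle_spikes <- function(v, eta = 3, w = 5, mad_floor = 1e-9,
                          mad_rel_floor = 0.1) {
  n <- length(v); h <- (w - 1) %/% 2
  m <- sapply(seq_len(n), function(k) {
    nb <- v[max(1, k - h):min(n, k + h)]
    nb <- nb[!is.na(nb)]
    if (!length(nb)) NA_real_ else median(nb)
  })
  dev <- abs(v - m)
  mad <- median(dev[!is.na(dev)])
  if (!is.na(mad) && mad == 0) {
    rng <- diff(range(v[!is.na(v)]))
    mad <- max(mad_floor, mad_rel_floor * rng)
  }
  which(!is.na(dev) & dev > eta * mad)
}
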