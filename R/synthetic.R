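#' Configuration for the clean trend generator
#'
#' Trend-level vitals at 1 Hz are emulated as a baseline plus a few slow
#' sinusoids (random phases, periods drawn from
#' \code{harmonic_period_range_s}) plus a slow AR(1) drift generated on a
#' coarse 60-s knot grid and resampled through a natural cubic spline.
#' Component amplitudes are scaled so the total sd is
#' \code{trend_sd_fraction} times the clinical radius, and the result is
#' clamped to the signal's clinical range.
#'
#' @param signal_id signal identifier (must have clinical bounds).
#' @param duration_s stream duration in seconds (>= 1).
#' @param sample_interval_s sampling interval, default 1 s.
#' @param baseline mean level; default the clinical midpoint.
#' @param n_harmonics number of slow sinusoids, default 3.
#' @param harmonic_period_range_s period range in seconds, default
#'   \code{c(300, 1800)}.
#' @param trend_sd_fraction total sd as a fraction of the clinical radius,
#'   default 0.3.
#' @param seed integer seed.
#' @return list of class \code{"trend_config"}.
#' @export
trend_config <- function(signal_id, duration_s,
                         sample_interval_s = 1,
                         baseline = NULL,
                         n_harmonics = 3,
                         harmonic_period_range_s = c(300, 1800),
                         trend_sd_fraction = 0.3,
                         seed = 1L) {
  if (duration_s < 1) stop("duration_s must be >= 1")
  if (trend_sd_fraction < 0 || trend_sd_fraction > 1)
    stop("trend_sd_fraction must lie in [0, 1]")
  if (diff(harmonic_period_range_s) < 0)
    stop("harmonic_period_range_s must be ordered")
  structure(list(signal_id = toupper(signal_id), duration_s = duration_s,
                 sample_interval_s = sample_interval_s, baseline = baseline,
                 n_harmonics = n_harmonics,
                 harmonic_period_range_s = harmonic_period_range_s,
                 trend_sd_fraction = trend_sd_fraction,
                 seed = as.integer(seed)),
            class = "trend_config")
}

#' Generate a clean trend-level vital-sign stream
#'
#' Deterministic given \code{cfg$seed}; all values lie inside the signal's
#' clinical range \code{[L, U]} (clamped after construction).
#'
#' @param cfg a \code{\link{trend_config}}.
#' @param bounds a \code{\link{clinical_bounds}} table.
#' @return A clean \code{\link{signal_stream}} of length
#'   \code{duration_s / sample_interval_s}.
#' @export
generate_clean_stream <- function(cfg, bounds = clinical_bounds()) {
  b <- bounds_row(bounds, cfg$signal_id)
  n <- floor(cfg$duration_s / cfg$sample_interval_s)
  t <- (seq_len(n) - 1L) * cfg$sample_interval_s
  baseline <- if (is.null(cfg$baseline)) b$C else cfg$baseline
  sd_target <- cfg$trend_sd_fraction * b$R

  v <- local_seed(cfg$seed, {
    out <- rep(baseline, n)
    if (sd_target > 0) {
      # harmonics carry ~80% of the variance, the slow AR(1) drift ~60%
      # (0.8^2 + 0.6^2 = 1); harmonic amplitudes are randomly proportioned
      if (cfg$n_harmonics > 0) {
        periods <- stats::runif(cfg$n_harmonics,
                                cfg$harmonic_period_range_s[1],
                                cfg$harmonic_period_range_s[2])
        phases <- stats::runif(cfg$n_harmonics, 0, 2 * pi)
        w <- stats::runif(cfg$n_harmonics, 0.5, 1)
        # sd of A*sin is A/sqrt(2); normalise sum of variances
        amp <- w * sqrt((0.8 * sd_target)^2 / sum(w^2 / 2))
        for (i in seq_len(cfg$n_harmonics))
          out <- out + amp[i] * sin(2 * pi * t / periods[i] + phases[i])
      }
      # slow AR(1) drift on a 60-s knot grid, spline-resampled to the
      # stream rate so the drift is C2-smooth at 1 Hz
      knot_dt <- 60
      kt <- seq(0, max(t) + knot_dt, by = knot_dt)
      phi <- 0.9
      innov_sd <- 0.6 * sd_target * sqrt(1 - phi^2)
      d <- numeric(length(kt))
      d[1] <- stats::rnorm(1, 0, 0.6 * sd_target)
      for (i in seq_along(kt)[-1])
        d[i] <- phi * d[i - 1] + stats::rnorm(1, 0, innov_sd)
      out <- out + stats::spline(kt, d, xout = t, method = "natural")$y
    }
    out
  })
  v <- pmin(pmax(v, b$L), b$U)
  signal_stream(v, cfg$signal_id, cfg$sample_interval_s, 0, "clean")
}

#' Resample a coarse record onto a fine uniform grid
#'
#' Maps sparse knots (e.g. 10-minute records) onto a continuous-time
#' trajectory with a natural cubic spline (C2-continuous, zero second
#' derivatives at the ends) and samples it at \code{target_interval_s}. Knot
#' values are reproduced exactly at knot times.
#'
#' @param knots data.frame or matrix with columns (time_s, value), or a list
#'   with \code{time_s} and \code{value}; >= 2 knots with strictly increasing
#'   times.
#' @param target_interval_s target sampling interval in seconds.
#' @param signal_id identifier for the resulting stream (default "X").
#' @return A clean \code{\link{signal_stream}} covering
#'   \code{[min(time), max(time)]}.
#' @export
resample_coarse_to_stream <- function(knots, target_interval_s,
                                      signal_id = "X") {
  knots <- as.data.frame(knots)
  names(knots)[1:2] <- c("time_s", "value")
  if (nrow(knots) < 2) stop("need at least 2 knots")
  if (any(diff(knots$time_s) <= 0))
    stop("knot times must be strictly increasing (no duplicates)")
  xout <- seq(knots$time_s[1], knots$time_s[nrow(knots)],
              by = target_interval_s)
  y <- stats::spline(knots$time_s, knots$value, xout = xout,
                     method = "natural")$y
  signal_stream(y, signal_id, target_interval_s, knots$time_s[1], "clean")
}

#' Configuration of the strong WBAN degradation model
#'
#' Defaults reproduce the strong corruption regime: 20--30\% burst
#' missingness per window (bursts up to 15 s), additive Gaussian noise with
#' sd 8\% of the clinical range, baseline wander at 0.5 cycles per window,
#' 5\% impulse spikes at \eqn{\pm 4\sigma}, linear drift of
#' \eqn{0.15\sigma} per window (accumulating across windows), soft clipping
#' near the clinical bounds, and rounding to 0.2-unit precision.
#' \eqn{\sigma} here is the additive-noise sd
#' (\code{noise_sd_fraction_of_range} times the clinical range; 1\% of the
#' range when the noise component is disabled), the scale the degradation
#' model is phrased in.
#'
#' @param missing_fraction_range per-window missing fraction range,
#'   default \code{c(0.20, 0.30)}.
#' @param max_burst_s maximum burst length in seconds, default 15.
#' @param noise_sd_fraction_of_range Gaussian noise sd as a fraction of the
#'   clinical range, default 0.08.
#' @param wander_cycles_per_window baseline-wander frequency, default 0.5.
#' @param wander_amplitude_sd_fraction wander amplitude in units of the
#'   clean window sd, default 0.5.
#' @param spike_probability per-sample impulse probability, default 0.05.
#' @param spike_amplitude_sd impulse amplitude in window sds, default 4.
#' @param drift_sd_fraction_per_window accumulated drift per window in
#'   window sds, default 0.15.
#' @param quantization_step rounding precision, default 0.2; 0 disables
#'   quantization.
#' @param soft_clip apply soft saturation near the clinical bounds, default
#'   TRUE.
#' @param seed integer seed.
#' @return list of class \code{"degradation_config"}.
#' @export
degradation_config <- function(missing_fraction_range = c(0.20, 0.30),
                               max_burst_s = 15,
                               noise_sd_fraction_of_range = 0.08,
                               wander_cycles_per_window = 0.5,
                               wander_amplitude_sd_fraction = 0.5,
                               spike_probability = 0.05,
                               spike_amplitude_sd = 4,
                               drift_sd_fraction_per_window = 0.15,
                               quantization_step = 0.2,
                               soft_clip = TRUE,
                               seed = 1L) {
  fr <- missing_fraction_range
  if (any(fr < 0) || any(fr > 1) || diff(fr) < 0)
    stop("missing_fraction_range must be an ordered pair in [0, 1]")
  if (spike_probability < 0 || spike_probability > 1)
    stop("spike_probability must lie in [0, 1]")
  if (quantization_step < 0) stop("quantization_step must be >= 0")
  structure(list(missing_fraction_range = fr, max_burst_s = max_burst_s,
                 noise_sd_fraction_of_range = noise_sd_fraction_of_range,
                 wander_cycles_per_window = wander_cycles_per_window,
                 wander_amplitude_sd_fraction = wander_amplitude_sd_fraction,
                 spike_probability = spike_probability,
                 spike_amplitude_sd = spike_amplitude_sd,
                 drift_sd_fraction_per_window = drift_sd_fraction_per_window,
                 quantization_step = quantization_step,
                 soft_clip = soft_clip, seed = as.integer(seed)),
            class = "degradation_config")
}

# independent substream seed per signal and corruption component, so toggling
# one component never reshuffles the draws of another
component_seed <- function(seed, signal_id, component) {
  h <- sum(utf8ToInt(paste0(signal_id, ":", component)) *
             seq_len(nchar(signal_id) + nchar(component) + 1L))
  (as.integer(seed) * 1009L + as.integer(h %% 99991L)) %% .Machine$integer.max
}

#' Inject the strong WBAN degradation model into a clean stream
#'
#' Applies, per disjoint window of \code{window_len_s}: additive Gaussian
#' noise, sinusoidal baseline wander, impulse spikes, accumulating linear
#' drift, soft clipping near the clinical bounds (reusing the logistic
#' saturation curve), quantization, and burst missingness. Every applied
#' corruption is recorded in a per-sample mask. Reproducible given
#' \code{cfg$seed}.
#'
#' @param clean a clean \code{\link{signal_stream}}.
#' @param cfg a \code{\link{degradation_config}}.
#' @param window_len_s degradation window length in seconds (default 50);
#'   must not exceed the stream length.
#' @param bounds a \code{\link{clinical_bounds}} table.
#' @return list with \code{stream} (corrupted \code{signal_stream}) and
#'   \code{mask} (logical matrix, one row per sample, columns
#'   \code{missing}, \code{noise}, \code{spike}, \code{clipped},
#'   \code{drift}, \code{quantized}).
#' @export
inject_degradation <- function(clean, cfg, window_len_s = 50,
                               bounds = clinical_bounds()) {
  if (attr(clean, "provenance") != "clean")
    stop("input stream must have clean provenance")
  n <- length(clean)
  dt <- attr(clean, "sample_interval_s")
  nw <- round(window_len_s / dt)
  if (nw > n) stop("window_len_s exceeds the stream length")
  sid <- attr(clean, "signal_id")
  b <- bounds_row(bounds, sid)
  span <- b$U - b$L
  v <- as.numeric(clean)
  mask <- matrix(FALSE, n, 6,
                 dimnames = list(NULL, c("missing", "noise", "spike",
                                         "clipped", "drift", "quantized")))

  starts <- seq(1L, n, by = nw)
  # sigma scale for wander/spike/drift magnitudes: the additive-noise sd
  # (the sigma the degradation model is phrased in); 1% of the clinical
  # range when the noise component is disabled so spikes/drift still exist
  sig_deg <- if (cfg$noise_sd_fraction_of_range > 0)
    cfg$noise_sd_fraction_of_range * span else 0.01 * span
  sig_w <- rep(sig_deg, length(starts))

  # additive Gaussian noise
  if (cfg$noise_sd_fraction_of_range > 0) {
    noise <- local_seed(component_seed(cfg$seed, sid, "noise"),
                        stats::rnorm(n, 0, cfg$noise_sd_fraction_of_range * span))
    v <- v + noise
    mask[, "noise"] <- TRUE
  }

  # low-frequency baseline wander, per window
  if (cfg$wander_amplitude_sd_fraction > 0 && cfg$wander_cycles_per_window > 0) {
    local_seed(component_seed(cfg$seed, sid, "wander"), {
      for (i in seq_along(starts)) {
        idx <- starts[i]:min(starts[i] + nw - 1L, n)
        amp <- cfg$wander_amplitude_sd_fraction * sig_w[i]
        ph <- stats::runif(1, 0, 2 * pi)
        v[idx] <- v[idx] + amp *
          sin(2 * pi * cfg$wander_cycles_per_window *
                (seq_along(idx) - 1L) / nw + ph)
      }
    })
  }

  # impulse spikes
  if (cfg$spike_probability > 0 && cfg$spike_amplitude_sd > 0) {
    local_seed(component_seed(cfg$seed, sid, "spike"), {
      hit <- stats::runif(n) < cfg$spike_probability
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      for (i in seq_along(starts)) {
        idx <- starts[i]:min(starts[i] + nw - 1L, n)
        a <- cfg$spike_amplitude_sd * sig_w[i]
        v[idx] <- v[idx] + ifelse(hit[idx], sgn[idx] * a, 0)
      }
      mask[, "spike"] <- hit
    })
  }

  # linear drift, accumulating across windows
  if (cfg$drift_sd_fraction_per_window > 0) {
    local_seed(component_seed(cfg$seed, sid, "drift"), {
      offset <- 0
      for (i in seq_along(starts)) {
        idx <- starts[i]:min(starts[i] + nw - 1L, n)
        step <- stats::rnorm(1, 0, cfg$drift_sd_fraction_per_window * sig_w[i])
        ramp <- offset + step * (seq_along(idx) - 1L) / max(length(idx) - 1L, 1L)
        v[idx] <- v[idx] + ramp
        offset <- offset + step
      }
      mask[, "drift"] <- TRUE
    })
  }

  # soft clipping: logistic saturation applied outside a 5% margin
  if (isTRUE(cfg$soft_clip)) {
    lo <- b$L + 0.05 * span
    hi <- b$U - 0.05 * span
    out <- v < lo | v > hi
    if (any(out)) {
      clipped <- b$L + span * stats::plogis((v[out] - b$b) / b$a)
      mask[out, "clipped"] <- abs(clipped - v[out]) > 1e-12
      v[out] <- clipped
    }
  }

  # quantization
  if (cfg$quantization_step > 0) {
    v <- round(v / cfg$quantization_step) * cfg$quantization_step
    mask[, "quantized"] <- TRUE
  }

  # burst missingness, per window
  if (cfg$missing_fraction_range[2] > 0) {
    local_seed(component_seed(cfg$seed, sid, "missing"), {
      for (i in seq_along(starts)) {
        idx <- starts[i]:min(starts[i] + nw - 1L, n)
        nwin <- length(idx)
        f <- stats::runif(1, cfg$missing_fraction_range[1],
                          cfg$missing_fraction_range[2])
        target <- round(f * nwin)
        drop <- logical(nwin)
        guard <- 0L
        while (sum(drop) < target && guard < 200L) {
          guard <- guard + 1L
          need <- target - sum(drop)
          len <- if (stats::runif(1) < 0.5) 1L else
            sample.int(max(1L, min(cfg$max_burst_s, need)), 1L)
          s0 <- sample.int(max(1L, nwin - len + 1L), 1L)
          drop[s0:(s0 + len - 1L)] <- TRUE
        }
        # trim overshoot from the end of the last burst so the per-window
        # fraction stays inside the configured range
        if (sum(drop) > target) {
          excess <- sum(drop) - target
          on <- which(drop)
          drop[on[(length(on) - excess + 1L):length(on)]] <- FALSE
        }
        v[idx][drop] <- NA_real_
        mask[idx, "missing"] <- drop
      }
    })
  }

  list(stream = restamp_stream(clean, v, "corrupted"), mask = mask)
}

#' Simulate a cohort of paired clean/corrupted vital-sign streams
#'
#' Generates one clean stream per signal (baselines drawn uniformly within
#' \eqn{C \pm 0.6R} to emulate inter-patient variability, so clinical-bound
#' contacts actually occur) and injects the strong degradation model.
#'
#' @param duration_s stream duration per signal, in seconds.
#' @param signals character vector of signal ids, default all seven vitals.
#' @param seed master integer seed.
#' @param degradation a \code{\link{degradation_config}} (its seed is derived
#'   from \code{seed} per signal).
#' @param bounds a \code{\link{clinical_bounds}} table.
#' @param window_len_s degradation window length, default 50 s.
#' @param trend_sd_fraction passed to \code{\link{trend_config}}.
#' @param baseline_spread half-width of the baseline draw in clinical radii,
#'   default 0.6.
#' @return list of class \code{"vitalgate_sim"} with elements \code{clean},
#'   \code{corrupted}, \code{mask} (named per signal), plus the configs used.
#' @export
simulate_vitals <- function(duration_s = 3600,
                            signals = c("HR", "SPO2", "RR", "TEMP",
                                        "SYS", "DIA", "GLU"),
                            seed = 1L,
                            degradation = degradation_config(),
                            bounds = clinical_bounds(),
                            window_len_s = 50,
                            trend_sd_fraction = 0.3,
                            baseline_spread = 0.6) {
  signals <- toupper(signals)
  clean <- corrupted <- mask <- stats::setNames(vector("list", length(signals)),
                                                signals)
  for (i in seq_along(signals)) {
    sid <- signals[i]
    b <- bounds_row(bounds, sid)
    sseed <- component_seed(seed, sid, "trend")
    baseline <- local_seed(component_seed(seed, sid, "baseline"),
                           stats::runif(1, b$C - baseline_spread * b$R,
                                        b$C + baseline_spread * b$R))
    cfg <- trend_config(sid, duration_s, baseline = baseline,
                        trend_sd_fraction = trend_sd_fraction, seed = sseed)
    clean[[sid]] <- generate_clean_stream(cfg, bounds)
    dcfg <- degradation
    dcfg$seed <- component_seed(seed, sid, "degrade")
    deg <- inject_degradation(clean[[sid]], dcfg, window_len_s, bounds)
    corrupted[[sid]] <- deg$stream
    mask[[sid]] <- deg$mask
  }
  structure(list(clean = clean, corrupted = corrupted, mask = mask,
                 bounds = bounds, degradation = degradation, seed = seed,
                 duration_s = duration_s),
            class = "vitalgate_sim")
}

#' @export
print.vitalgate_sim <- function(x, ...) {
  cat(sprintf("<vitalgate_sim: %d signals x %d s, seed %d>\n",
              length(x$clean), x$duration_s, x$seed))
  invisible(x)
}
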