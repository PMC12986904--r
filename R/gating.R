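#' Gating (corruption-detection) parameters
#'
#' @param kappa IQR fence multiplier, default 1.5.
#' @param delta_samples gate expansion width in samples, default 2.
#' @param eta spike threshold multiplier for the MAD, default 3.
#' @param median_window rolling-median width in samples (odd, >= 3),
#'   default 5.
#' @param mad_floor absolute floor substituted when the window MAD is zero,
#'   default 1e-9.
#' @param mad_rel_floor relative floor (fraction of the window's valid-value
#'   range) also applied when the MAD is zero, default 0.1; keeps benign
#'   curvature of smooth trends from being flagged while still catching
#'   spikes on otherwise constant segments (whose range is zero).
#' @return list of class \code{"gate_params"}.
#' @export
gate_params <- function(kappa = 1.5, delta_samples = 2, eta = 3,
                        median_window = 5, mad_floor = 1e-9,
                        mad_rel_floor = 0.1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (delta_samples < 0) stop("delta_samples must be >= 0")
  if (eta <= 0) stop("eta must be > 0")
  if (median_window < 3 || median_window %% 2 == 0)
    stop("median_window must be odd and >= 3")
  structure(list(kappa = kappa, delta_samples = as.integer(delta_samples),
                 eta = eta, median_window = as.integer(median_window),
                 mad_floor = mad_floor, mad_rel_floor = mad_rel_floor),
            class = "gate_params")
}

#' IQR fences for outlier gating
#'
#' Returns \code{c(Q1 - kappa*IQR, Q3 + kappa*IQR)} computed on the valid
#' (non-missing) samples with linear-interpolation (type 7) quartiles.
#'
#' @param values numeric vector (NA = missing); needs >= 4 valid samples.
#' @param kappa fence multiplier.
#' @return numeric length-2 vector (lower, upper).
#' @export
#' @examples
#' iqr_fences(c(1, 2, 3, 4, 5), 1.5)  # c(-1, 7)
iqr_fences <- function(values, kappa = 1.5) {
  v <- values[!is.na(values)]
  if (length(v) < 4)
    stop(structure(class = c("vitalgate_degenerate_window", "error",
                             "condition"),
                   list(message = "fewer than 4 valid samples: IQR fences undefined",
                        call = sys.call())))
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(q[1] - kappa * iqr, q[2] + kappa * iqr)
}

# rolling median over the truncated neighbourhood [k - h, k + h] (center
# included), using valid samples only; NA where the neighbourhood has no
# valid sample
rolling_median <- function(values, width) {
  n <- length(values)
  h <- (width - 1L) %/% 2L
  vapply(seq_len(n), function(k) {
    w <- values[max(1L, k - h):min(n, k + h)]
    w <- w[!is.na(w)]
    if (!length(w)) NA_real_ else stats::median(w)
  }, numeric(1))
}

#' Spike flags from a rolling median and window-level MAD
#'
#' Flags indices where \code{|z - m| > eta * MAD}, with \code{m} the rolling
#' median over \code{median_window} valid samples (truncated at window
#' boundaries) and MAD the window-level median absolute deviation about
#' \code{m}. A zero MAD is replaced by
#' \code{max(mad_floor, mad_rel_floor * range(valid values))}.
#' Missing samples are never flagged here (they gate through the missing
#' component).
#'
#' @param values numeric vector (NA = missing), length >= median_window.
#' @param params a \code{\link{gate_params}}.
#' @return integer vector of flagged (1-based) indices.
#' @export
spike_flags <- function(values, params = gate_params()) {
  if (length(values) < params$median_window)
    stop("need at least median_window samples")
  m <- rolling_median(values, params$median_window)
  dev <- abs(values - m)
  ok <- !is.na(dev)
  if (!any(ok)) return(integer(0))
  mad <- stats::median(dev[ok])
  if (mad == 0) {
    v <- values[!is.na(values)]
    rng <- if (length(v)) diff(range(v)) else 0
    mad <- max(params$mad_floor, params$mad_rel_floor * rng)
  }
  which(ok & dev > params$eta * mad)
}

#' Build the gate mask for one window
#'
#' The anomaly set A is the union of out-of-fence samples, spike-flagged
#' samples and missing samples; the gate set G expands A by
#' \code{delta_samples} on each side (truncated to the window); the gating
#' rate is \code{rho = |G| / N}. Windows with fewer than 4 valid samples
#' skip the IQR component (quartiles undefined); missingness and spikes
#' still gate. Gating operates on raw, pre-interpolation values.
#'
#' @param window a window from \code{\link{segment_stream}}, or a numeric
#'   vector.
#' @param params a \code{\link{gate_params}}.
#' @return list of class \code{"gate_mask"}: \code{anomaly} (sorted indices,
#'   1-based), \code{gate}, \code{low_confidence} (filled later by
#'   \code{\link{fill_gaps}}), \code{rho}, \code{n}.
#' @export
build_gate <- function(window, params = gate_params()) {
  v <- if (is.list(window)) window$values else as.numeric(window)
  n <- length(v)
  miss <- which(is.na(v))
  fence_idx <- tryCatch({
    f <- iqr_fences(v, params$kappa)
    which(!is.na(v) & (v < f[1] | v > f[2]))
  }, vitalgate_degenerate_window = function(e) integer(0))
  spikes <- if (n >= params$median_window) spike_flags(v, params) else integer(0)
  a <- sort(unique(c(fence_idx, spikes, miss)))
  g <- if (length(a)) {
    sort(unique(unlist(lapply(a, function(t)
      max(1L, t - params$delta_samples):min(n, t + params$delta_samples)))))
  } else integer(0)
  structure(list(anomaly = a, gate = g, low_confidence = integer(0),
                 rho = length(g) / n, n = n),
            class = "gate_mask")
}

#' @export
print.gate_mask <- function(x, ...) {
  cat(sprintf("<gate_mask: |A|=%d |G|=%d rho=%.3f of N=%d>\n",
              length(x$anomaly), length(x$gate), x$rho, x$n))
  invisible(x)
}
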