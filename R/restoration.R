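#' Restoration parameters
#'
#' @param gap_threshold_s maximum gap length filled by the spline, default
#'   5 s; longer gaps fall back to last-value imputation and are marked
#'   low-confidence.
#' @param Q 2x2 EKF process covariance, default \code{diag(c(0.01, 0.001))}.
#' @param R_base base measurement noise variance, default 0.5.
#' @param lambda_skip measurement-noise inflation factor on gated indices,
#'   default 1e3 (\code{Inf} skips the update entirely).
#' @param lambda_gap inflation factor on long-gap (low-confidence)
#'   imputations, default equal to \code{lambda_skip}.
#' @param smoothing_radius local median half-width in samples, default 2.
#' @param dt sampling interval in seconds, default 1.
#' @return list of class \code{"restoration_params"}.
#' @export
restoration_params <- function(gap_threshold_s = 5,
                               Q = diag(c(0.01, 0.001)),
                               R_base = 0.5,
                               lambda_skip = 1e3,
                               lambda_gap = lambda_skip,
                               smoothing_radius = 2,
                               dt = 1) {
  if (gap_threshold_s <= 0 || R_base <= 0 || lambda_skip <= 0 ||
      lambda_gap <= 0 || smoothing_radius <= 0 || dt <= 0)
    stop("all restoration parameters must be positive")
  Q <- as.matrix(Q)
  if (!isTRUE(all.equal(Q, t(Q))) || any(eigen(Q, only.values = TRUE)$values < -1e-12))
    stop("Q must be symmetric positive semidefinite")
  structure(list(gap_threshold_s = gap_threshold_s, Q = Q, R_base = R_base,
                 lambda_skip = lambda_skip, lambda_gap = lambda_gap,
                 smoothing_radius = as.integer(smoothing_radius), dt = dt),
            class = "restoration_params")
}

#' Fill missing samples in a window
#'
#' Gaps no longer than \code{gap_threshold_s / dt} samples are filled with
#' the natural cubic spline through the window's valid samples; longer gaps
#' are filled by last-valid-observation carry-forward (first-valid backward
#' fill for a leading gap) and their indices are returned as
#' \code{low_confidence} so the EKF can inflate their measurement noise.
#' Valid samples are returned unchanged.
#'
#' @param window a window from \code{\link{segment_stream}} or a numeric
#'   vector with NA gaps; needs >= 2 valid samples.
#' @param params a \code{\link{restoration_params}}.
#' @return list with \code{filled} (complete numeric vector) and
#'   \code{low_confidence} (1-based indices).
#' @export
fill_gaps <- function(window, params = restoration_params()) {
  v <- if (is.list(window)) window$values else as.numeric(window)
  n <- length(v)
  valid <- which(!is.na(v))
  if (length(valid) < 2)
    stop(structure(class = c("vitalgate_unrecoverable_window", "error",
                             "condition"),
                   list(message = "fewer than 2 valid samples in window",
                        call = sys.call())))
  if (length(valid) == n) return(list(filled = v, low_confidence = integer(0)))
  max_gap <- round(params$gap_threshold_s / params$dt)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  low_conf <- integer(0)
  short_idx <- integer(0)
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    if (r$lengths[i] <= max_gap) short_idx <- c(short_idx, idx)
    else low_conf <- c(low_conf, idx)
  }
  filled <- v
  if (length(short_idx))
    filled[short_idx] <- stats::spline(valid, v[valid], xout = short_idx,
                                       method = "natural")$y
  if (length(low_conf)) filled[low_conf] <- locf_fill(filled)[low_conf]
  # a short gap adjacent to nothing can only arise at the window edges where
  # the spline extrapolates linearly; that is intended (natural boundary)
  list(filled = filled, low_confidence = low_conf)
}

new_ekf_state <- function(x, P) list(x = as.numeric(x), P = as.matrix(P))

# default first-window initialisation: latent level from the inverse
# logistic of the first valid sample, zero slope, diffuse covariance
init_ekf_state <- function(first_value, bounds, params,
                           measurement = "logistic") {
  s0 <- if (measurement == "logistic")
    inverse_logistic_measure(first_value, bounds) else first_value
  new_ekf_state(c(s0, 0), diag(c(params$R_base * 10, 0.1)))
}

#' Forward extended Kalman filter with selective (gated) updates
#'
#' Constant-velocity latent dynamics \eqn{x_k = [s_k, v_k]}, F =
#' [[1, dt], [0, 1]], with the bounded logistic measurement model
#' \eqn{h(s) = L + (U-L)\sigma((s-b)/a)} (or the identity measurement for
#' the linear-KF ablation). On gated or low-confidence indices the
#' measurement noise is inflated to \code{lambda_skip * R_base}
#' (\code{lambda_gap * R_base} for long-gap imputations; \code{Inf} skips
#' the update), so the filter coasts on its dynamics through corrupted
#' regions and trusts the data elsewhere. Estimates are returned in
#' physical units, \code{estimates[k] = h(s_{k|k})}.
#'
#' @param filled complete numeric measurement vector (no NA).
#' @param gate a \code{\link{build_gate}} mask (or integer vector of gated
#'   indices).
#' @param low_confidence indices of long-gap imputations.
#' @param bounds one row of \code{\link{clinical_bounds}}.
#' @param params a \code{\link{restoration_params}}.
#' @param init optional \code{ekf} state carried from the previous window
#'   (list with \code{x}, \code{P}).
#' @param measurement \code{"logistic"} (default) or \code{"identity"}.
#' @param carry_index index whose posterior state is additionally returned
#'   as \code{carry_state} for cross-window hand-off (default the stride
#'   boundary is chosen by the caller; here defaults to the last index).
#' @return list with \code{estimates} (physical units), \code{gamma}
#'   (down-weighted fraction), \code{final_state}, \code{carry_state},
#'   \code{nis} (normalised innovation squared on full-weight updates) and
#'   \code{n_full_updates}.
#' @export
ekf_filter <- function(filled, gate, low_confidence = integer(0),
                       bounds, params = restoration_params(),
                       init = NULL, measurement = c("logistic", "identity"),
                       carry_index = length(filled)) {
  measurement <- match.arg(measurement)
  if (anyNA(filled) || any(!is.finite(filled)))
    stop("ekf_filter requires complete finite measurements")
  g <- if (is.list(gate)) gate$gate else as.integer(gate)
  n <- length(filled)
  dt <- params$dt
  FF <- matrix(c(1, 0, dt, 1), 2, 2)
  logistic <- measurement == "logistic"

  if (is.null(init))
    init <- init_ekf_state(filled[1], bounds, params, measurement)
  x <- init$x
  P <- init$P

  down <- logical(n)
  down[g] <- TRUE
  lam <- rep(1, n)
  lam[g] <- params$lambda_skip
  lam[low_confidence] <- pmax(lam[low_confidence], params$lambda_gap)
  down[low_confidence] <- TRUE

  est <- numeric(n)
  nis <- rep(NA_real_, n)
  carry_state <- NULL
  # latent-state projection: keep s inside the invertible part of the
  # logistic curve (|u| <= logit(0.99)); beyond it the measurement Jacobian
  # vanishes and the filter can never be pulled back from saturation
  u_max <- stats::qlogis(0.99)
  clamp_s <- function(x) {
    if (!logistic) return(x)
    x[1] <- min(max(x[1], bounds$b - u_max * bounds$a),
                bounds$b + u_max * bounds$a)
    x
  }
  for (k in seq_len(n)) {
    # predict
    x <- clamp_s(c(x[1] + x[2] * dt, x[2]))
    P <- FF %*% P %*% t(FF) + params$Q
    Rk <- lam[k] * params$R_base
    if (is.finite(Rk)) {
      if (logistic) {
        hk <- logistic_measure(x[1], bounds)
        H <- c(measurement_jacobian(x[1], bounds), 0)
      } else {
        hk <- x[1]
        H <- c(1, 0)
      }
      innov <- filled[k] - hk
      S <- drop(t(H) %*% P %*% H) + Rk
      K <- (P %*% H) / S
      x <- clamp_s(x + drop(K) * innov)
      P <- (diag(2) - K %*% t(H)) %*% P
      if (!down[k]) nis[k] <- innov^2 / S
    }
    # guard numerical symmetry loss
    if (max(abs(P - t(P))) > 1e-8) P <- (P + t(P)) / 2
    est[k] <- if (logistic) logistic_measure(x[1], bounds) else x[1]
    if (k == carry_index) carry_state <- new_ekf_state(x, P)
  }
  if (is.null(carry_state)) carry_state <- new_ekf_state(x, P)
  list(estimates = est, gamma = mean(down),
       final_state = new_ekf_state(x, P), carry_state = carry_state,
       nis = nis, n_full_updates = sum(!down))
}

#' Gated local median smoothing
#'
#' For each gated index k the output is the median of the EKF estimates over
#' the truncated neighbourhood \code{[k - radius, k + radius]}; samples
#' outside the gate are returned unchanged.
#'
#' @param estimates complete numeric vector (EKF output).
#' @param gate a \code{\link{build_gate}} mask or integer index vector.
#' @param params a \code{\link{restoration_params}} (uses
#'   \code{smoothing_radius}).
#' @return numeric vector, same length.
#' @export
gated_median_smooth <- function(estimates, gate,
                                params = restoration_params()) {
  g <- if (is.list(gate)) gate$gate else as.integer(gate)
  if (!length(g)) return(estimates)
  n <- length(estimates)
  h <- params$smoothing_radius
  out <- estimates
  for (k in g)
    out[k] <- stats::median(estimates[max(1L, k - h):min(n, k + h)])
  out
}

#' Merge restored samples with untouched raw samples
#'
#' The selectivity contract: output[k] equals \code{smoothed[k]} for gated or
#' missing k and is bit-identical to the raw input elsewhere.
#'
#' @param raw the original window (list or numeric vector, NA = missing).
#' @param smoothed complete numeric vector after gated smoothing.
#' @param gate a \code{\link{build_gate}} mask.
#' @return list of class \code{"restored_window"}: \code{values},
#'   \code{gate}.
#' @export
reconstruct_window <- function(raw, smoothed, gate) {
  v <- if (is.list(raw)) raw$values else as.numeric(raw)
  if (length(v) != length(smoothed)) stop("length mismatch")
  g <- if (is.list(gate)) gate$gate else as.integer(gate)
  miss <- which(is.na(v))
  if (length(setdiff(miss, g)))
    stop("internal error: missing sample not covered by the gate")
  out <- v
  out[g] <- smoothed[g]
  if (anyNA(out)) stop("internal error: missing values after reconstruction")
  structure(list(values = out, gate = gate), class = "restored_window")
}

#' Restore a full corrupted stream window-by-window
#'
#' Runs the whole restoration cascade over overlapping windows with EKF
#' state carry-over: per window, gate detection on the raw samples, spline
#' gap filling, the gated EKF (initialised from the state recorded at the
#' previous window's stride boundary so overlapping samples are not
#' double-propagated), gated median smoothing and the selective merge. The
#' stream-level restored series takes window 1 in full and from each later
#' window its trailing stride-new samples.
#'
#' All-missing (unrecoverable) windows carry the previous state forward and
#' emit a flat continuation at the last restored level; their samples are
#' fully gated and marked low-confidence.
#'
#' @param corrupted a corrupted \code{\link{signal_stream}}.
#' @param plan a \code{\link{window_plan}}.
#' @param gating a \code{\link{gate_params}}.
#' @param params a \code{\link{restoration_params}}.
#' @param bounds a \code{\link{clinical_bounds}} table.
#' @param measurement \code{"logistic"} or \code{"identity"} (linear-KF
#'   ablation).
#' @param process_all gate every sample (process-all ablation: the EKF
#'   updates all samples at full weight and smoothing covers the whole
#'   window), default FALSE. Missing samples are still down-weighted.
#' @return list of class \code{"restored_stream"}: \code{stream} (restored
#'   \code{signal_stream}), \code{windows} (per-window list: \code{gate},
#'   \code{gamma}, \code{raw}, \code{filled}, \code{ekf}, \code{smoothed},
#'   \code{restored}, \code{nis}, \code{n_full_updates}), \code{rho_avg},
#'   \code{gamma_avg}, \code{plan}.
#' @export
restore_stream <- function(corrupted, plan = window_plan(),
                           gating = gate_params(),
                           params = restoration_params(),
                           bounds = clinical_bounds(),
                           measurement = c("logistic", "identity"),
                           process_all = FALSE) {
  measurement <- match.arg(measurement)
  b <- bounds_row(bounds, attr(corrupted, "signal_id"))
  wins <- segment_stream(corrupted, plan)
  ns <- plan$n_samples
  stride <- plan$stride_samples
  carry <- NULL
  last_level <- NULL
  out_windows <- vector("list", length(wins))
  restored_full <- rep(NA_real_, length(corrupted))

  for (w in seq_along(wins)) {
    win <- wins[[w]]
    gate <- build_gate(win, gating)
    if (process_all) {
      gate$gate <- seq_len(ns)
      gate$rho <- 1
    }
    res <- tryCatch({
      fg <- fill_gaps(win, params)
      gate$low_confidence <- fg$low_confidence
      ek <- ekf_filter(fg$filled, gate, fg$low_confidence, b, params,
                       init = carry, measurement = measurement,
                       carry_index = stride)
      # under process-all, gating no longer marks corruption: update at
      # full weight everywhere except genuine missing/low-confidence fills
      if (process_all) {
        miss <- which(is.na(win$values))
        ek <- ekf_filter(fg$filled, sort(unique(c(miss, fg$low_confidence))),
                         fg$low_confidence, b, params, init = carry,
                         measurement = measurement, carry_index = stride)
      }
      sm <- gated_median_smooth(ek$estimates, gate, params)
      rw <- reconstruct_window(win, sm, gate)
      list(fg = fg, ek = ek, sm = sm, rw = rw, ok = TRUE)
    }, vitalgate_unrecoverable_window = function(e) NULL)

    if (is.null(res)) {
      # unrecoverable: flat continuation at the carried level
      level <- if (!is.null(last_level)) last_level else b$C
      gate$gate <- seq_len(ns)
      gate$low_confidence <- seq_len(ns)
      gate$rho <- 1
      flat <- rep(level, ns)
      ek <- list(estimates = flat, gamma = 1,
                 final_state = carry, carry_state = carry,
                 nis = rep(NA_real_, ns), n_full_updates = 0L)
      res <- list(fg = list(filled = flat, low_confidence = seq_len(ns)),
                  ek = ek, sm = flat,
                  rw = structure(list(values = flat, gate = gate),
                                 class = "restored_window"),
                  ok = FALSE)
    }
    carry <- res$ek$carry_state
    last_level <- res$rw$values[ns]

    out_windows[[w]] <- list(index = w, start_sample = win$start_sample,
                             gate = gate, gamma = res$ek$gamma,
                             raw = win$values, filled = res$fg$filled,
                             ekf = res$ek$estimates, smoothed = res$rw$values,
                             nis = res$ek$nis,
                             n_full_updates = res$ek$n_full_updates,
                             recovered = res$ok)

    idx <- win$start_sample:(win$start_sample + ns - 1L)
    if (w == 1L) restored_full[idx] <- res$rw$values
    else {
      new <- (ns - stride + 1L):ns
      restored_full[idx[new]] <- res$rw$values[new]
    }
  }
  # trailing samples beyond the last full window keep their raw values
  tail_na <- which(is.na(restored_full))
  if (length(tail_na)) restored_full[tail_na] <- locf_fill(as.numeric(corrupted))[tail_na]

  structure(list(stream = restamp_stream(corrupted, restored_full, "restored"),
                 windows = out_windows,
                 rho_avg = mean(vapply(out_windows, function(w) w$gate$rho,
                                       numeric(1))),
                 gamma_avg = mean(vapply(out_windows, function(w) w$gamma,
                                         numeric(1))),
                 plan = plan),
            class = "restored_stream")
}

#' @export
print.restored_stream <- function(x, ...) {
  cat(sprintf("<restored_stream %s: %d windows, rho_avg=%.3f gamma_avg=%.3f>\n",
              attr(x$stream, "signal_id"), length(x$windows), x$rho_avg,
              x$gamma_avg))
  invisible(x)
}
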