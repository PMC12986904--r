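#' Percentage MSE gain between two stages
#'
#' \code{100 * (1 - mse_after / mse_before)}; computed relative to the
#' preceding stage, rounded only at report time.
#'
#' @param mse_before,mse_after stage MSEs; \code{mse_before > 0}.
#' @return percent gain (can be negative if the stage hurts).
#' @export
#' @examples
#' stage_gain(2345.18, 1237.66)  # ~47.2
stage_gain <- function(mse_before, mse_after) {
  if (any(mse_before <= 0)) stop("mse_before must be > 0")
  100 * (1 - mse_after / mse_before)
}

#' Range-normalized MAE and RMSE
#'
#' Both series are min-max scaled to [0, 1] using the corrupted window's
#' observed range before the errors are computed, enabling cross-signal
#' averaging on a common scale.
#'
#' @param estimate,truth numeric vectors of equal length.
#' @param corrupted the corrupted reference series whose range defines the
#'   scaling (NAs ignored); must have a positive range.
#' @return named numeric vector \code{c(MAE =, RMSE =)}.
#' @export
normalized_errors <- function(estimate, truth, corrupted) {
  if (length(estimate) != length(truth)) stop("length mismatch")
  rng <- range(corrupted, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop(structure(class = c("vitalgate_zero_range", "error", "condition"),
                   list(message = "corrupted range is zero; window skipped",
                        call = sys.call())))
  sc <- function(x) (x - rng[1]) / diff(rng)
  e <- sc(estimate) - sc(truth)
  c(MAE = mean(abs(e)), RMSE = sqrt(mean(e^2)))
}

#' Forecast-quality metrics
#'
#' window-MAE (mean absolute forecast error), directional accuracy (sign of
#' the predicted change vs the actual change relative to the last observed
#' value, with a no-change band of 1e-6), slope error (mean absolute
#' difference between predicted and actual per-stride slope) and empirical
#' prediction-interval coverage.
#'
#' @param forecasts list of \code{\link{forecast_one_step}} results (or a
#'   data.frame with columns point, pi_low, pi_high).
#' @param actuals realized values at the forecast targets.
#' @param last_observed last observed value before each forecast.
#' @param stride_s stride length used for the slope, default 10.
#' @return named numeric vector: window_MAE, directional_accuracy,
#'   slope_error, pi_coverage.
#' @export
forecast_metrics <- function(forecasts, actuals, last_observed,
                             stride_s = 10) {
  if (!length(actuals)) stop("empty input")
  if (is.data.frame(forecasts)) {
    point <- forecasts$point; lo <- forecasts$pi_low; hi <- forecasts$pi_high
  } else {
    point <- vapply(forecasts, `[[`, numeric(1), "point")
    lo <- vapply(forecasts, `[[`, numeric(1), "pi_low")
    hi <- vapply(forecasts, `[[`, numeric(1), "pi_high")
  }
  stopifnot(length(point) == length(actuals),
            length(actuals) == length(last_observed))
  band <- 1e-6
  dsign <- function(x) ifelse(abs(x) < band, 0, sign(x))
  dir_ok <- dsign(point - last_observed) == dsign(actuals - last_observed)
  c(window_MAE = mean(abs(point - actuals)),
    directional_accuracy = mean(dir_ok),
    slope_error = mean(abs((point - last_observed) / stride_s -
                             (actuals - last_observed) / stride_s)),
    pi_coverage = mean(actuals >= lo & actuals <= hi))
}

#' Rates derived from pooled confusion counts
#'
#' TPR, TNR, FPR, FNR, balanced accuracy \code{(TPR+TNR)/2} and Youden's J
#' \code{TPR+TNR-1}. Rates with an empty class are reported as NA.
#'
#' @param counts a \code{\link{classify_and_count}} result (or list with
#'   TP, FP, TN, FN).
#' @return named numeric vector.
#' @export
#' @examples
#' confusion_metrics(list(TP = 89, FN = 11, TN = 92, FP = 8))
confusion_metrics <- function(counts) {
  if (any(unlist(counts[c("TP", "FP", "TN", "FN")]) < 0))
    stop("counts must be >= 0")
  tpr <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
         else NA_real_
  tnr <- if (counts$TN + counts$FP > 0) counts$TN / (counts$TN + counts$FP)
         else NA_real_
  c(TPR = tpr, TNR = tnr, FPR = 1 - tnr, FNR = 1 - tpr,
    balanced_accuracy = (tpr + tnr) / 2, youden_j = tpr + tnr - 1)
}

#' Lead times between alerts and subsequent events
#'
#' For each event, the lead is \code{event_time - max(alert <= event)} among
#' alerts within \code{horizon_s} before the event. Events with no such
#' alert are counted as missed and excluded from the lead statistics.
#'
#' @param alert_times,event_times sorted numeric times in seconds.
#' @param horizon_s matching horizon, default 120 s.
#' @return list with \code{leads} (per matched event), \code{n_missed},
#'   \code{mean}, \code{median}.
#' @export
lead_times <- function(alert_times, event_times, horizon_s = 120) {
  leads <- numeric(0)
  missed <- 0L
  for (ev in event_times) {
    prior <- alert_times[alert_times <= ev & alert_times >= ev - horizon_s]
    if (length(prior)) leads <- c(leads, ev - max(prior))
    else missed <- missed + 1L
  }
  list(leads = leads, n_missed = missed,
       mean = if (length(leads)) mean(leads) else NA_real_,
       median = if (length(leads)) stats::median(leads) else NA_real_)
}

#' Paired stage tests on subsampled window MSEs
#'
#' Uniformly samples \code{n_sample} window pairs without replacement
#' (seeded; the same indices for both tests), then runs a paired t-test and
#' a Wilcoxon signed-rank test, two-sided. Identical stages (all
#' differences zero) degenerate to p = 1.
#'
#' @param mse_a,mse_b per-window MSE vectors of equal length >=
#'   \code{n_sample}.
#' @param n_sample number of windows to sample, default 997.
#' @param seed sampling seed.
#' @return named numeric vector \code{c(p_t =, p_wilcoxon =)}.
#' @export
paired_stage_tests <- function(mse_a, mse_b, n_sample = 997, seed = 1L) {
  if (length(mse_a) != length(mse_b)) stop("length mismatch")
  if (length(mse_a) < n_sample) stop("fewer windows than n_sample")
  idx <- local_seed(seed, sample.int(length(mse_a), n_sample))
  a <- mse_a[idx]; b <- mse_b[idx]
  d <- a - b
  if (all(d == 0)) return(c(p_t = 1, p_wilcoxon = 1))
  # a constant nonzero improvement has zero variance: the t statistic
  # diverges, so the two-sided p-value is 0
  p_t <- if (stats::sd(d) == 0) 0
         else stats::t.test(a, b, paired = TRUE)$p.value
  p_w <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE)$p.value)
  c(p_t = p_t, p_wilcoxon = p_w)
}

#' Computational savings implied by the gating rate
#'
#' Under gated operation only the fraction rho of samples triggers
#' restoration, so the expected saving is \code{100 * (1 - rho)} percent.
#'
#' @param rho gating rate in [0, 1].
#' @return percent savings.
#' @export
#' @examples
#' savings_factor(0.214)  # 78.6
savings_factor <- function(rho) {
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  100 * (1 - rho)
}
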