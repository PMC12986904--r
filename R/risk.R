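#' Risk-scoring configuration
#'
#' @param alpha weight of the statistical deviation term, default 0.1 (the
#'   clinical term gets 1 - alpha).
#' @param thresholds named per-signal alert thresholds tau_j; defaults
#'   RR 0.15, TEMP 0.55, SYS 0.45, DIA 0.50, HR 0.75, SPO2 0.90, GLU 0.75.
#' @param tau_global global (aggregate-risk) alert threshold, default 0.35.
#' @param sd_floor floor for the window sd in the statistical term, default
#'   1e-6.
#' @param aggregator \code{"mean"} (default) or \code{"sum"}.
#' @return list of class \code{"risk_config"}.
#' @export
risk_config <- function(alpha = 0.1,
                        thresholds = c(RR = 0.15, TEMP = 0.55, SYS = 0.45,
                                       DIA = 0.50, HR = 0.75, SPO2 = 0.90,
                                       GLU = 0.75),
                        tau_global = 0.35, sd_floor = 1e-6,
                        aggregator = c("mean", "sum")) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (any(thresholds < 0 | thresholds > 1))
    stop("per-signal thresholds must lie in [0, 1]")
  structure(list(alpha = alpha, thresholds = thresholds,
                 tau_global = tau_global, sd_floor = sd_floor,
                 aggregator = match.arg(aggregator)),
            class = "risk_config")
}

#' Clinical-aware deviation score
#'
#' \deqn{Z = \alpha |f - \mu| / \sigma + (1-\alpha) \min(|f - C| / R, 1)}
#' blending the statistical deviation of the forecast \code{f} from the
#' window mean/sd with its clinical deviation from the midpoint \code{C}
#' in units of the clinical radius \code{R} (capped at 1).
#'
#' @param forecast forecasted value.
#' @param mu,sigma mean and sd of the restored data in the current window.
#' @param bounds one row of \code{\link{clinical_bounds}}.
#' @param alpha statistical weight, default 0.1.
#' @param sd_floor sigma floor, default 1e-6.
#' @return nonnegative deviation score Z.
#' @export
#' @examples
#' b <- clinical_bounds("HR")
#' deviation_score(100, mu = 80, sigma = 10, b)  # 0.1*2 + 0.9*1 = 1.1
deviation_score <- function(forecast, mu, sigma, bounds, alpha = 0.1,
                            sd_floor = 1e-6) {
  if (sigma < 0) stop("sigma must be >= 0")
  sigma <- max(sigma, sd_floor)
  alpha * abs(forecast - mu) / sigma +
    (1 - alpha) * pmin(abs(forecast - bounds$C) / bounds$R, 1.0)
}

#' Clip a deviation score to the unit risk scale
#'
#' \code{min(Z, 1)}; bounds every modality's contribution so no single
#' vital sign can dominate the aggregate.
#'
#' @param Z nonnegative deviation score(s).
#' @return clipped risk in [0, 1].
#' @export
clip_risk <- function(Z) {
  if (any(Z < 0)) stop("deviation scores must be >= 0")
  pmin(Z, 1.0)
}

#' Aggregate per-signal clipped risks
#'
#' Unweighted mean (default) of the available per-signal clipped risks;
#' \code{"sum"} is available but no longer bounded by 1.
#'
#' @param per_signal_r named numeric vector of clipped risks in [0, 1].
#' @param aggregator \code{"mean"} or \code{"sum"}.
#' @return aggregate risk.
#' @export
aggregate_risk <- function(per_signal_r, aggregator = c("mean", "sum")) {
  aggregator <- match.arg(aggregator)
  r <- per_signal_r[!is.na(per_signal_r)]
  if (!length(r)) stop("no per-signal risks to aggregate")
  if (any(r < 0 | r > 1)) stop("clipped risks must lie in [0, 1]")
  if (aggregator == "mean") mean(r) else sum(r)
}

#' Pooled confusion counts for thresholded risk scores
#'
#' Micro-averaging: predictions are \code{risk >= threshold}, pooled over
#' all windows into a single confusion matrix.
#'
#' @param risks numeric risk scores.
#' @param threshold decision threshold.
#' @param truth binary (0/1 or logical) ground-truth event labels, same
#'   length.
#' @return list of class \code{"confusion_counts"} with TP, FP, TN, FN.
#' @export
classify_and_count <- function(risks, threshold, truth) {
  if (length(risks) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  if (anyNA(truth)) stop("truth must be binary")
  pred <- risks >= threshold
  structure(list(TP = sum(pred & truth), FP = sum(pred & !truth),
                 TN = sum(!pred & !truth), FN = sum(!pred & truth)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d FP=%d TN=%d FN=%d>\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
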