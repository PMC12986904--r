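#' Forecasting configuration
#'
#' Per-window ARIMA(1,1,1) with a stationarity fallback to ARIMA(1,0,0):
#' near-constant windows (sd of the first-differenced series below a
#' per-signal threshold) and windows the augmented Dickey-Fuller test calls
#' stationary are fitted without differencing. Thresholds: HR 0.1,
#' SpO2 0.05; other signals default to 0.002 x clinical range.
#'
#' @param order default ARIMA order, \code{c(1, 1, 1)}.
#' @param history_len recent-history length W used for fitting, default 50.
#' @param fallback_std_threshold named numeric vector of per-signal
#'   differenced-sd thresholds; missing signals get
#'   \code{0.002 * (U - L)}.
#' @param adf_alpha ADF significance level, default 0.05.
#' @param pi_level central prediction-interval level, default 0.95.
#' @param horizon forecast horizon in samples, default 1 (the pipeline uses
#'   one stride).
#' @return list of class \code{"forecast_config"}.
#' @export
forecast_config <- function(order = c(1, 1, 1), history_len = 50,
                            fallback_std_threshold = c(HR = 0.1, SPO2 = 0.05),
                            adf_alpha = 0.05, pi_level = 0.95, horizon = 1) {
  if (history_len < 10) stop("history_len must be >= 10")
  if (pi_level <= 0 || pi_level >= 1) stop("pi_level must lie in (0, 1)")
  structure(list(order = order, history_len = as.integer(history_len),
                 fallback_std_threshold = fallback_std_threshold,
                 adf_alpha = adf_alpha, pi_level = pi_level,
                 horizon = as.integer(horizon)),
            class = "forecast_config")
}

fallback_threshold <- function(cfg, signal_id, bounds) {
  sid <- toupper(signal_id)
  th <- cfg$fallback_std_threshold
  if (sid %in% names(th)) return(unname(th[sid]))
  b <- tryCatch(bounds_row(bounds, sid), error = function(e) NULL)
  if (is.null(b)) 0.05 else 0.002 * (b$U - b$L)
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Regression of the first difference on the lagged level, a constant, a
#' linear trend and \code{k} lagged differences (lag order
#' \code{trunc((n-1)^(1/3))} by default). The p-value interpolates the
#' standard Dickey-Fuller tau critical-value table (Banerjee et al., 1993).
#' Small p-values reject the unit-root null, i.e. indicate stationarity.
#'
#' @param x numeric series, length >= 10.
#' @param k lag order; default \code{trunc((length(x) - 1)^(1/3))}.
#' @return list with \code{statistic} and \code{p.value} (clamped to
#'   [0.01, 0.99], the table's range).
#' @export
adf_test <- function(x, k = trunc((length(x) - 1)^(1/3))) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("need at least 10 observations")
  if (stats::sd(x) == 0)
    return(list(statistic = 0, p.value = 0.99))
  k <- max(0L, as.integer(k))
  dx <- diff(x)
  m <- length(dx)
  rows <- (k + 1L):m
  y <- dx[rows]
  lagged <- x[rows]             # x_{t-1} aligned with dx_t
  tt <- rows
  X <- cbind(1, lagged, tt)
  if (k > 0) {
    lags <- sapply(seq_len(k), function(j) dx[rows - j])
    X <- cbind(X, lags)
  }
  stat <- tryCatch({
    fit <- stats::lm.fit(X, y)
    res <- fit$residuals
    df <- length(y) - ncol(X)
    s2 <- sum(res^2) / df
    XtX_inv <- chol2inv(chol(crossprod(X)))
    fit$coefficients[2] / sqrt(s2 * XtX_inv[2, 2])
  }, error = function(e) NA_real_)
  # a degenerate (collinear) regression arises on near-constant segments;
  # treat them as stationary so the forecaster falls back to AR(1)
  if (!is.finite(stat)) return(list(statistic = NA_real_, p.value = 0.01))
  # Dickey-Fuller tau (constant + trend) critical values
  tbl <- -cbind(c(4.38, 4.15, 4.04, 3.99, 3.98, 3.96),
                c(3.95, 3.80, 3.73, 3.69, 3.68, 3.66),
                c(3.60, 3.50, 3.45, 3.43, 3.42, 3.41),
                c(3.24, 3.18, 3.15, 3.13, 3.13, 3.12),
                c(1.14, 1.19, 1.22, 1.23, 1.24, 1.25),
                c(0.80, 0.87, 0.90, 0.92, 0.93, 0.94),
                c(0.50, 0.58, 0.62, 0.64, 0.65, 0.66),
                c(0.15, 0.24, 0.28, 0.31, 0.32, 0.33))
  tblN <- c(25, 50, 100, 250, 500, 1e5)
  tblP <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  crit <- vapply(seq_along(tblP), function(j)
    stats::approx(tblN, tbl[, j], xout = n, rule = 2)$y, numeric(1))
  p <- stats::approx(crit, tblP, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p.value = unname(p))
}

#' Select the per-window ARIMA order
#'
#' Returns \code{c(1, 0, 0)} when the window is near-constant (sd of the
#' first-differenced series below the per-signal threshold) or when the ADF
#' test rejects the unit-root null (the series is already stationary);
#' otherwise \code{c(1, 1, 1)}.
#'
#' @param series complete numeric series, length >= 10.
#' @param cfg a \code{\link{forecast_config}}.
#' @param signal_id signal identifier (for the threshold lookup).
#' @param bounds a \code{\link{clinical_bounds}} table.
#' @return integer vector (p, d, q).
#' @export
select_order <- function(series, cfg = forecast_config(), signal_id = "HR",
                         bounds = clinical_bounds()) {
  if (length(series) < 10) stop("series too short (< 10)")
  if (anyNA(series)) stop("series must be complete")
  th <- fallback_threshold(cfg, signal_id, bounds)
  if (stats::sd(diff(series)) < th) return(c(1L, 0L, 0L))
  adf <- adf_test(series)
  if (adf$p.value > cfg$adf_alpha) c(1L, 1L, 1L) else c(1L, 0L, 0L)
}

fit_arima <- function(y, order) {
  stats::arima(y, order = order, include.mean = order[2] == 0,
               method = "CSS-ML")
}

#' One-step-ahead forecast with prediction interval
#'
#' Fits the selected ARIMA order by maximum likelihood on the most recent
#' \code{history_len} samples and returns the \code{horizon}-step point
#' forecast with its central \code{pi_level} prediction interval. Optimiser
#' failures fall back to ARIMA(1,0,0), then to a naive last-value forecast
#' with interval \code{+/- 2 sd(diff(series))}.
#'
#' @param series complete numeric series (restored window history).
#' @param cfg a \code{\link{forecast_config}}.
#' @param signal_id signal identifier.
#' @param bounds a \code{\link{clinical_bounds}} table.
#' @param horizon forecast horizon in samples; default \code{cfg$horizon}.
#' @return list of class \code{"forecast_result"}: \code{point},
#'   \code{pi_low}, \code{pi_high}, \code{order_used}, \code{phi1},
#'   \code{theta1}, \code{fallback} (character tag).
#' @export
forecast_one_step <- function(series, cfg = forecast_config(),
                              signal_id = "HR", bounds = clinical_bounds(),
                              horizon = cfg$horizon) {
  series <- as.numeric(series)
  if (anyNA(series)) stop("series must be complete")
  y <- utils::tail(series, cfg$history_len)
  if (length(y) < 10) stop("need at least 10 samples of history")
  order <- select_order(y, cfg, signal_id, bounds)
  z <- stats::qnorm(0.5 + cfg$pi_level / 2)
  fallback <- "none"

  fit <- tryCatch(suppressWarnings(fit_arima(y, order)),
                  error = function(e) NULL)
  if (is.null(fit) && !identical(order, c(1L, 0L, 0L))) {
    order <- c(1L, 0L, 0L)
    fallback <- "ar1"
    fit <- tryCatch(suppressWarnings(fit_arima(y, order)),
                    error = function(e) NULL)
  }
  if (is.null(fit)) {
    sdd <- stats::sd(diff(y))
    if (!is.finite(sdd)) sdd <- 0
    point <- y[length(y)]
    return(structure(list(point = point, pi_low = point - 2 * sdd,
                          pi_high = point + 2 * sdd,
                          order_used = c(0L, 0L, 0L),
                          phi1 = NA_real_, theta1 = NA_real_,
                          fallback = "naive"),
                     class = "forecast_result"))
  }
  pr <- stats::predict(fit, n.ahead = horizon)
  point <- as.numeric(pr$pred[horizon])
  se <- as.numeric(pr$se[horizon])
  co <- stats::coef(fit)
  structure(list(point = point,
                 pi_low = point - z * se, pi_high = point + z * se,
                 order_used = order,
                 phi1 = if ("ar1" %in% names(co)) unname(co["ar1"]) else NA_real_,
                 theta1 = if ("ma1" %in% names(co)) unname(co["ma1"]) else NA_real_,
                 fallback = fallback),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast %.3f [%.3f, %.3f] ARIMA(%d,%d,%d)%s>\n",
              x$point, x$pi_low, x$pi_high, x$order_used[1], x$order_used[2],
              x$order_used[3],
              if (x$fallback != "none") paste0(" fallback=", x$fallback) else ""))
  invisible(x)
}
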