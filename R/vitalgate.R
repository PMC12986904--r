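#' Pipeline configuration
#'
#' Bundles every stage's parameters with their default operating point:
#' T = 50 s windows, S = 10 s stride, 1 Hz sampling; kappa = 1.5, delta = 2,
#' eta = 3; gap threshold 5 s; Q = diag(0.01, 0.001), R = 0.5; ARIMA(1,1,1)
#' with fallback; alpha = 0.1 risk blending.
#'
#' @param plan a \code{\link{window_plan}}.
#' @param gating a \code{\link{gate_params}}.
#' @param restoration a \code{\link{restoration_params}}.
#' @param forecast a \code{\link{forecast_config}}; its horizon defaults to
#'   one stride.
#' @param risk a \code{\link{risk_config}}.
#' @param bounds a \code{\link{clinical_bounds}} table.
#' @param measurement \code{"logistic"} (EKF, default) or \code{"identity"}
#'   (linear-KF ablation).
#' @param process_all process-all ablation switch, default FALSE.
#' @param run_forecast fit the forecasting stage, default TRUE (stage
#'   isolation: restoration output is produced either way).
#' @return list of class \code{"vitalgate_config"}.
#' @export
vitalgate_config <- function(plan = window_plan(),
                             gating = gate_params(),
                             restoration = restoration_params(),
                             forecast = NULL,
                             risk = risk_config(),
                             bounds = clinical_bounds(),
                             measurement = c("logistic", "identity"),
                             process_all = FALSE,
                             run_forecast = TRUE) {
  if (is.null(forecast))
    forecast <- forecast_config(history_len = plan$n_samples,
                                horizon = plan$stride_samples)
  structure(list(plan = plan, gating = gating, restoration = restoration,
                 forecast = forecast, risk = risk, bounds = bounds,
                 measurement = match.arg(measurement),
                 process_all = isTRUE(process_all),
                 run_forecast = isTRUE(run_forecast)),
            class = "vitalgate_config")
}

as_stream_list <- function(data) {
  if (inherits(data, "vitalgate_sim")) return(data$corrupted)
  if (inherits(data, "signal_stream")) {
    out <- list(data); names(out) <- attr(data, "signal_id"); return(out)
  }
  if (is.data.frame(data)) return(streams_from_frame(data, "corrupted"))
  if (is.list(data)) return(data)
  stop("cannot interpret 'data' as vital-sign streams")
}

#' Run the full selective-restoration and early-warning pipeline
#'
#' The main entry point. For each signal the corrupted stream is segmented
#' into overlapping windows; corrupted samples are gated (IQR fences,
#' rolling-median/MAD spikes, missingness), restored (spline fill, gated
#' EKF with the bounded logistic sensor model and cross-window state
#' carry-over, gated median smoothing) and merged with the untouched raw
#' samples. Each restored window is forecast one stride ahead with adaptive
#' ARIMA(1,1,1) and mapped to a clipped clinical risk score; per-window
#' risks are aggregated across signals into a global alert. When ground
#' truth is available (a \code{\link{simulate_vitals}} object, or
#' \code{truth} supplied) the full evaluation report is attached.
#'
#' @param data corrupted input: a \code{\link{simulate_vitals}} result, a
#'   named list of corrupted \code{\link{signal_stream}}s, or a data.frame
#'   with a \code{time_s} column (empty/NA = missing).
#' @param truth optional clean ground truth in the same shape.
#' @param config a \code{\link{vitalgate_config}}.
#' @return An object of class \code{"vitalgate"} with components
#'   \code{windows} (per signal/window data.frame: rho, gamma, ARIMA order,
#'   forecast, risk, alert, event), \code{aggregate} (per-window global
#'   risk/alert/event), \code{restored}, \code{corrupted}, \code{clean},
#'   \code{metrics} (NULL without truth), \code{config}.
#' @seealso \code{\link{summary.vitalgate}}, \code{\link{predict.vitalgate}}
#' @export
#' @examples
#' sim <- simulate_vitals(600, signals = c("HR", "SPO2"), seed = 1)
#' fit <- vitalgate(sim)
#' summary(fit)
vitalgate <- function(data, truth = NULL, config = vitalgate_config()) {
  corrupted <- as_stream_list(data)
  clean <- if (!is.null(truth)) as_stream_list(truth)
           else if (inherits(data, "vitalgate_sim")) data$clean else NULL
  signals <- names(corrupted)
  plan <- config$plan
  stride <- plan$stride_samples
  ns <- plan$n_samples

  restored <- vector("list", length(signals)); names(restored) <- signals
  rows <- list()
  for (sid in signals) {
    rs <- restore_stream(corrupted[[sid]], plan, config$gating,
                         config$restoration, config$bounds,
                         measurement = config$measurement,
                         process_all = config$process_all)
    restored[[sid]] <- rs
    b <- bounds_row(config$bounds, sid)
    cl <- if (!is.null(clean)) as.numeric(clean[[sid]]) else NULL
    n_stream <- length(corrupted[[sid]])

    for (w in seq_along(rs$windows)) {
      win <- rs$windows[[w]]
      end_idx <- win$start_sample + ns - 1L
      target <- end_idx + stride
      fc <- NULL
      if (config$run_forecast) {
        fc <- tryCatch(
          forecast_one_step(win$smoothed, config$forecast, sid,
                            config$bounds, horizon = stride),
          error = function(e) NULL)
      }
      mu <- mean(win$smoothed); sdw <- stats::sd(win$smoothed)
      z_r <- r <- NA_real_
      if (!is.null(fc)) {
        z_r <- deviation_score(fc$point, mu, sdw, b, config$risk$alpha,
                               config$risk$sd_floor)
        r <- clip_risk(z_r)
      }
      actual <- event <- r_truth <- NA
      if (!is.null(cl) && target <= n_stream) {
        actual <- cl[target]
        ev_idx <- (end_idx + 1L):target
        event <- any(cl[ev_idx] <= b$L | cl[ev_idx] >= b$U)
        if (!is.null(fc))
          r_truth <- clip_risk(deviation_score(actual, mu, sdw, b,
                                               config$risk$alpha,
                                               config$risk$sd_floor))
      }
      tau <- config$risk$thresholds[sid]
      rows[[length(rows) + 1L]] <- data.frame(
        signal = sid, window = w, start_sample = win$start_sample,
        end_time_s = stream_times(corrupted[[sid]])[end_idx],
        rho = win$gate$rho, gamma = win$gamma,
        n_full_updates = win$n_full_updates,
        order = if (is.null(fc)) NA_character_ else
          paste(fc$order_used, collapse = ","),
        point = if (is.null(fc)) NA_real_ else fc$point,
        pi_low = if (is.null(fc)) NA_real_ else fc$pi_low,
        pi_high = if (is.null(fc)) NA_real_ else fc$pi_high,
        Z = z_r, risk = r,
        alert = if (is.na(r) || is.na(tau)) NA else r >= tau,
        actual = actual, risk_truth = r_truth, event = event,
        stringsAsFactors = FALSE)
    }
  }
  windows <- do.call(rbind, rows)

  # aggregate risk per window index across signals
  agg <- NULL
  if (config$run_forecast) {
    widx <- sort(unique(windows$window))
    agg <- do.call(rbind, lapply(widx, function(w) {
      sub <- windows[windows$window == w, , drop = FALSE]
      r <- stats::setNames(sub$risk, sub$signal)
      a <- if (all(is.na(r))) NA_real_
           else aggregate_risk(r[!is.na(r)], config$risk$aggregator)
      ev <- if (all(is.na(sub$event))) NA else any(sub$event, na.rm = TRUE)
      data.frame(window = w, end_time_s = sub$end_time_s[1],
                 aggregate = a,
                 alert = if (is.na(a)) NA else a >= config$risk$tau_global,
                 event = ev)
    }))
  }

  fit <- structure(list(windows = windows, aggregate = agg,
                        restored = restored, corrupted = corrupted,
                        clean = clean,
                        mask = if (inherits(data, "vitalgate_sim")) data$mask
                               else NULL,
                        metrics = NULL, config = config,
                        call = match.call()),
                   class = "vitalgate")
  if (!is.null(clean)) fit$metrics <- evaluate_fit(fit)
  fit
}

# stage series for one window: corrupted (gaps zero-order-filled),
# interpolated, gated-EKF merge, final smoothed merge
window_stage_series <- function(win) {
  g <- win$gate$gate
  ekf_stage <- win$raw
  ekf_stage[g] <- win$ekf[g]
  if (anyNA(ekf_stage)) ekf_stage[is.na(ekf_stage)] <- win$ekf[is.na(ekf_stage)]
  list(corrupted = locf_fill(win$raw), interpolated = win$filled,
       ekf = ekf_stage, smoothed = win$smoothed)
}

#' Evaluate a fitted pipeline against ground truth
#'
#' Computes the full report: per-signal stage MSEs (corrupted with gaps
#' zero-order-filled, interpolated, gated EKF, smoothed) with stage gains
#' and cumulative reduction, range-normalized MAE/RMSE, forecast metrics
#' (window-MAE, directional accuracy, slope error, PI coverage, risk
#' error), gating statistics (rho_avg, gamma, savings), per-signal and
#' pooled confusion metrics, lead times, and paired stage tests.
#'
#' @param fit a \code{\link{vitalgate}} object fitted with ground truth.
#' @param n_sample windows subsampled for the paired stage tests, default
#'   min(997, available).
#' @param seed sampling seed for the stage tests.
#' @return list of class \code{"vitalgate_metrics"}.
#' @export
evaluate_fit <- function(fit, n_sample = 997, seed = 1L) {
  if (is.null(fit$clean)) stop("evaluation requires ground truth")
  cfg <- fit$config
  plan <- cfg$plan
  ns <- plan$n_samples
  signals <- names(fit$restored)

  stage_names <- c("corrupted", "interpolated", "ekf", "smoothed")
  stage_tab <- NULL
  norm_tab <- NULL
  per_window_mse <- list()
  tests <- list()
  for (sid in signals) {
    cl <- as.numeric(fit$clean[[sid]])
    wins <- fit$restored[[sid]]$windows
    m <- sapply(wins, function(win) {
      truth <- cl[win$start_sample:(win$start_sample + ns - 1L)]
      st <- window_stage_series(win)
      vapply(st, mse, numeric(1), truth = truth)
    })
    per_window_mse[[sid]] <- m
    avg <- rowMeans(m)
    gain <- function(a, b) if (a > 0) stage_gain(a, b) else NA_real_
    stage_tab <- rbind(stage_tab, data.frame(
      signal = sid, t(avg),
      ekf_gain_pct = gain(avg["interpolated"], avg["ekf"]),
      smoothing_gain_pct = gain(avg["ekf"], avg["smoothed"]),
      cumulative_reduction_pct = gain(avg["corrupted"], avg["smoothed"]),
      stringsAsFactors = FALSE))
    ne <- t(sapply(wins, function(win) {
      truth <- cl[win$start_sample:(win$start_sample + ns - 1L)]
      tryCatch(normalized_errors(win$smoothed, truth, win$raw),
               vitalgate_zero_range = function(e) c(MAE = NA, RMSE = NA))
    }))
    norm_tab <- rbind(norm_tab, data.frame(
      signal = sid, MAE = mean(ne[, "MAE"], na.rm = TRUE),
      RMSE = mean(ne[, "RMSE"], na.rm = TRUE), stringsAsFactors = FALSE))
    nsub <- min(n_sample, ncol(m))
    tests[[sid]] <- rbind(
      corrupted_vs_interpolated =
        paired_stage_tests(m["corrupted", ], m["interpolated", ], nsub, seed),
      interpolated_vs_ekf =
        paired_stage_tests(m["interpolated", ], m["ekf", ], nsub, seed),
      ekf_vs_smoothed =
        paired_stage_tests(m["ekf", ], m["smoothed", ], nsub, seed))
  }
  rownames(stage_tab) <- NULL
  names(stage_tab)[2:5] <- paste0("mse_", stage_names)

  w <- fit$windows
  fc_tab <- conf_tab <- NULL
  pooled <- global_conf <- leads <- NULL
  if (cfg$run_forecast) {
    for (sid in signals) {
      sub <- w[w$signal == sid & !is.na(w$actual) & !is.na(w$point), ,
               drop = FALSE]
      if (!nrow(sub)) next
      last_obs <- vapply(seq_len(nrow(sub)), function(i) {
        win <- fit$restored[[sid]]$windows[[sub$window[i]]]
        win$smoothed[ns]
      }, numeric(1))
      fm <- forecast_metrics(sub[, c("point", "pi_low", "pi_high")],
                             sub$actual, last_obs, plan$stride_s)
      risk_err <- mean(abs(sub$risk - sub$risk_truth), na.rm = TRUE)
      fc_tab <- rbind(fc_tab, data.frame(signal = sid, t(fm),
                                         risk_error = risk_err,
                                         event_rate = mean(sub$event),
                                         stringsAsFactors = FALSE))
      cc <- classify_and_count(sub$risk, cfg$risk$thresholds[sid], sub$event)
      conf_tab <- rbind(conf_tab, data.frame(
        signal = sid, tau = unname(cfg$risk$thresholds[sid]),
        TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
        t(confusion_metrics(cc)), stringsAsFactors = FALSE))
    }
    agg <- fit$aggregate
    agg_ok <- agg[!is.na(agg$aggregate) & !is.na(agg$event), , drop = FALSE]
    if (nrow(agg_ok)) {
      pooled <- classify_and_count(agg_ok$aggregate, cfg$risk$tau_global,
                                   agg_ok$event)
      global_conf <- confusion_metrics(pooled)
      # event onsets: first bound contact of any signal
      ev_t <- sort(unique(unlist(lapply(signals, function(sid) {
        cl <- as.numeric(fit$clean[[sid]])
        b <- bounds_row(cfg$bounds, sid)
        out <- cl <= b$L | cl >= b$U
        onset <- which(out & !c(FALSE, out[-length(out)]))
        stream_times(fit$clean[[sid]])[onset]
      }))))
      al_t <- agg_ok$end_time_s[agg_ok$alert]
      leads <- lead_times(sort(al_t), ev_t)
    }
  }

  rho <- vapply(fit$restored, `[[`, numeric(1), "rho_avg")
  gamma <- vapply(fit$restored, `[[`, numeric(1), "gamma_avg")
  structure(list(stages = stage_tab, normalized = norm_tab,
                 forecast = fc_tab, confusion = conf_tab,
                 pooled_counts = pooled, global = global_conf,
                 lead_times = leads, stage_tests = tests,
                 per_window_mse = per_window_mse,
                 rho = rho, rho_avg = mean(rho),
                 gamma = gamma,
                 savings_pct = savings_factor(mean(rho))),
            class = "vitalgate_metrics")
}

#' @export
print.vitalgate <- function(x, ...) {
  cat(sprintf("vitalgate fit: %d signals, %d windows each (T=%gs, S=%gs)\n",
              length(x$restored),
              length(x$restored[[1]]$windows),
              x$config$plan$window_len_s, x$config$plan$stride_s))
  cat(sprintf("  gating rate rho_avg = %.3f (savings ~ %.1f%%)\n",
              mean(vapply(x$restored, `[[`, numeric(1), "rho_avg")),
              savings_factor(mean(vapply(x$restored, `[[`, numeric(1),
                                         "rho_avg")))))
  if (!is.null(x$metrics))
    cat(sprintf("  cumulative MSE reduction (mean) = %.1f%%\n",
                mean(x$metrics$stages$cumulative_reduction_pct)))
  invisible(x)
}

#' Summarise a fitted pipeline
#'
#' Prints the evaluation report (stage MSEs and gains, normalized errors,
#' forecast metrics, event detection, gating statistics) when ground truth
#' was available, otherwise the gating/forecast summary.
#'
#' @param object a \code{\link{vitalgate}} object.
#' @param digits significant digits for printing.
#' @param ... unused.
#' @return the metrics list (invisibly).
#' @export
summary.vitalgate <- function(object, digits = 4, ...) {
  print(object)
  m <- object$metrics
  if (is.null(m)) {
    cat("(no ground truth supplied: restoration/forecast outputs only)\n")
    return(invisible(NULL))
  }
  cat("\nStage MSE vs ground truth (per signal):\n")
  print(format(m$stages, digits = digits), row.names = FALSE)
  cat("\nRange-normalized errors (corrupted-window scaling):\n")
  print(format(m$normalized, digits = digits), row.names = FALSE)
  if (!is.null(m$forecast)) {
    cat("\nForecasting (one stride ahead):\n")
    print(format(m$forecast, digits = digits), row.names = FALSE)
  }
  if (!is.null(m$global)) {
    cat("\nGlobal event detection (aggregated risk):\n")
    print(round(m$global, 3))
    if (!is.null(m$lead_times) && length(m$lead_times$leads))
      cat(sprintf("Lead time: mean %.1f s, median %.1f s (%d missed)\n",
                  m$lead_times$mean, m$lead_times$median,
                  m$lead_times$n_missed))
  }
  cat(sprintf("\nGating: rho_avg = %.3f, savings ~ %.1f%%\n",
              m$rho_avg, m$savings_pct))
  invisible(m)
}

#' @export
coef.vitalgate <- function(object, ...) {
  w <- object$windows
  out <- do.call(rbind, lapply(split(w, w$signal), function(s) {
    b <- bounds_row(object$config$bounds, s$signal[1])
    data.frame(signal = s$signal[1], a = b$a, b = b$b,
               rho_avg = mean(s$rho), gamma_avg = mean(s$gamma),
               frac_arima111 = mean(s$order == "1,1,1", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Forecast the next stride from the end of each stream
#'
#' @param object a \code{\link{vitalgate}} object.
#' @param ... unused.
#' @return data.frame with one row per signal: point forecast, prediction
#'   interval and the ARIMA order used.
#' @export
predict.vitalgate <- function(object, ...) {
  cfg <- object$config
  do.call(rbind, lapply(names(object$restored), function(sid) {
    wins <- object$restored[[sid]]$windows
    last <- wins[[length(wins)]]
    fc <- forecast_one_step(last$smoothed, cfg$forecast, sid, cfg$bounds,
                            horizon = cfg$plan$stride_samples)
    data.frame(signal = sid, point = fc$point, pi_low = fc$pi_low,
               pi_high = fc$pi_high,
               order = paste(fc$order_used, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' @export
fitted.vitalgate <- function(object, ...) {
  lapply(object$restored, function(r) r$stream)
}

#' Residuals of the restoration
#'
#' \code{type = "restoration"}: corrupted minus restored (zero wherever the
#' gate passed raw samples through); \code{type = "truth"}: restored minus
#' clean ground truth (requires truth).
#'
#' @param object a \code{\link{vitalgate}} object.
#' @param type residual type.
#' @param ... unused.
#' @return named list of numeric vectors per signal.
#' @export
residuals.vitalgate <- function(object, type = c("restoration", "truth"),
                                ...) {
  type <- match.arg(type)
  if (type == "truth" && is.null(object$clean))
    stop("truth residuals require ground truth")
  lapply(stats::setNames(names(object$restored), names(object$restored)),
         function(sid) {
           r <- as.numeric(object$restored[[sid]]$stream)
           if (type == "restoration") as.numeric(object$corrupted[[sid]]) - r
           else r - as.numeric(object$clean[[sid]])
         })
}

#' Plot clean, corrupted and restored traces for one signal
#'
#' @param x a \code{\link{vitalgate}} object.
#' @param signal signal id (default the first).
#' @param xlim optional time range in seconds.
#' @param ... passed to \code{plot}.
#' @export
plot.vitalgate <- function(x, signal = names(x$restored)[1], xlim = NULL,
                           ...) {
  signal <- toupper(signal)
  corr <- x$corrupted[[signal]]
  rest <- x$restored[[signal]]$stream
  t <- stream_times(corr)
  if (is.null(xlim)) xlim <- range(t)
  keep <- t >= xlim[1] & t <= xlim[2]
  ylim <- range(c(corr[keep], rest[keep],
                  if (!is.null(x$clean)) x$clean[[signal]][keep]),
                na.rm = TRUE)
  graphics::plot(t[keep], corr[keep], type = "p", pch = 16, cex = 0.3,
                 col = "grey60", xlab = "time (s)", ylab = signal,
                 ylim = ylim, ...)
  if (!is.null(x$clean))
    graphics::lines(t[keep], x$clean[[signal]][keep], col = "black", lwd = 1)
  graphics::lines(t[keep], rest[keep], col = "firebrick", lwd = 1.2)
  graphics::legend("topright",
                   legend = c("corrupted", if (!is.null(x$clean)) "clean",
                              "restored"),
                   col = c("grey60", if (!is.null(x$clean)) "black",
                           "firebrick"),
                   lty = c(NA, if (!is.null(x$clean)) 1, 1),
                   pch = c(16, if (!is.null(x$clean)) NA, NA), bty = "n")
  invisible(x)
}
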