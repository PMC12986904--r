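#' Read vital-sign streams from CSV
#'
#' Schema: a \code{time_s} column plus one column per signal; empty cells
#' are missing samples (parsed as NA, never zero). Decimal point only
#' (locale-independent). The time step must be uniform.
#'
#' @param path CSV file path.
#' @param provenance provenance tag for the streams, default
#'   \code{"corrupted"}.
#' @return named list of \code{\link{signal_stream}}s.
#' @export
read_stream_csv <- function(path, provenance = "corrupted") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"time_s" %in% names(df)) stop("missing time_s column")
  dt <- unique(round(diff(df$time_s), 9))
  if (length(dt) != 1) stop("non-uniform time step in ", path)
  cols <- setdiff(names(df), "time_s")
  out <- lapply(cols, function(cn)
    signal_stream(df[[cn]], cn, dt, df$time_s[1], provenance))
  names(out) <- toupper(cols)
  out
}

#' Write vital-sign streams to CSV
#'
#' Inverse of \code{\link{read_stream_csv}}: missing samples become empty
#' cells; the roundtrip is lossless for values and missingness.
#'
#' @param streams named list of \code{\link{signal_stream}}s with equal
#'   length and timing.
#' @param path output CSV path.
#' @export
write_stream_csv <- function(streams, path) {
  t <- stream_times(streams[[1]])
  df <- data.frame(time_s = t)
  for (sid in names(streams)) {
    if (length(streams[[sid]]) != length(t)) stop("stream length mismatch")
    df[[sid]] <- as.numeric(streams[[sid]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

streams_from_frame <- function(df, provenance) {
  if (!"time_s" %in% names(df)) stop("missing time_s column")
  dt <- unique(round(diff(df$time_s), 9))
  if (length(dt) != 1) stop("non-uniform time step")
  cols <- setdiff(names(df), "time_s")
  out <- lapply(cols, function(cn)
    signal_stream(df[[cn]], cn, dt, df$time_s[1], provenance))
  names(out) <- toupper(cols)
  out
}

#' Write corruption masks to CSV
#'
#' One row per sample: \code{time_s} then per-signal cells holding
#' semicolon-separated flag tokens (subset of missing;noise;spike;clipped;
#' drift;quantized), empty when untouched.
#'
#' @param masks named list of logical mask matrices from
#'   \code{\link{inject_degradation}}.
#' @param times sample times in seconds.
#' @param path output path.
#' @export
write_mask_csv <- function(masks, times, path) {
  df <- data.frame(time_s = times)
  for (sid in names(masks)) {
    m <- masks[[sid]]
    df[[sid]] <- apply(m, 1, function(row)
      paste(colnames(m)[row], collapse = ";"))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-window gate masks to CSV
#'
#' Columns: signal, window, rho, and the gate set as a run-length-encoded
#' string (\code{start-end} runs joined by \code{";"}, 1-based).
#'
#' @param fit a \code{\link{vitalgate}} object.
#' @param path output path.
#' @export
write_gates_csv <- function(fit, path) {
  rows <- do.call(rbind, lapply(names(fit$restored), function(sid) {
    do.call(rbind, lapply(fit$restored[[sid]]$windows, function(win) {
      g <- win$gate$gate
      rle_str <- if (!length(g)) "" else {
        br <- c(0, which(diff(g) > 1), length(g))
        paste(vapply(seq_len(length(br) - 1), function(i) {
          seg <- g[(br[i] + 1):br[i + 1]]
          if (length(seg) == 1) as.character(seg)
          else paste0(seg[1], "-", seg[length(seg)])
        }, character(1)), collapse = ";")
      }
      data.frame(signal = sid, window = win$index, rho = win$gate$rho,
                 gate = rle_str, stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Load a pipeline configuration from YAML (or JSON)
#'
#' Any subset of the sections \code{plan}, \code{gating},
#' \code{restoration}, \code{forecast}, \code{risk}, \code{bounds} (a list
#' of signal: [L, U] pairs), \code{measurement}, \code{process_all} may be
#' given; omitted fields keep their defaults.
#'
#' @param path YAML or JSON file.
#' @return a \code{\link{vitalgate_config}}.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  plan <- do.call(window_plan, as.list(cfg$plan %||% list()))
  gating <- do.call(gate_params, as.list(cfg$gating %||% list()))
  restoration <- do.call(restoration_params,
                         as.list(cfg$restoration %||% list()))
  risk_args <- as.list(cfg$risk %||% list())
  if (!is.null(risk_args$thresholds))
    risk_args$thresholds <- unlist(risk_args$thresholds)
  risk <- do.call(risk_config, risk_args)
  bounds <- if (is.null(cfg$bounds)) clinical_bounds() else {
    ids <- names(cfg$bounds)
    clinical_bounds(ids, vapply(cfg$bounds, `[[`, numeric(1), 1),
                    vapply(cfg$bounds, `[[`, numeric(1), 2))
  }
  fc <- if (is.null(cfg$forecast)) NULL else {
    fa <- as.list(cfg$forecast)
    if (!is.null(fa$fallback_std_threshold))
      fa$fallback_std_threshold <- unlist(fa$fallback_std_threshold)
    do.call(forecast_config, fa)
  }
  vitalgate_config(plan = plan, gating = gating, restoration = restoration,
                   forecast = fc, risk = risk, bounds = bounds,
                   measurement = cfg$measurement %||% "logistic",
                   process_all = isTRUE(cfg$process_all))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
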