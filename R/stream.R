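#' Construct a signal stream
#'
#' A signal stream is one vital sign's uniformly sampled series, with
#' \code{NA} marking missing samples and a provenance tag saying whether the
#' values are clean ground truth, corrupted sensor output, or restored.
#'
#' @param values numeric vector (NA = missing).
#' @param signal_id character scalar, e.g. \code{"HR"}.
#' @param sample_interval_s sampling interval in seconds (default 1).
#' @param start_time_s time of the first sample in seconds (default 0).
#' @param provenance one of \code{"clean"}, \code{"corrupted"},
#'   \code{"restored"}.
#' @return An object of class \code{"signal_stream"}: the numeric vector with
#'   attributes.
#' @export
signal_stream <- function(values, signal_id,
                          sample_interval_s = 1, start_time_s = 0,
                          provenance = c("clean", "corrupted", "restored")) {
  provenance <- match.arg(provenance)
  if (length(values) < 1L) stop("stream must have length >= 1")
  if (sample_interval_s <= 0) stop("sample_interval_s must be positive")
  if (provenance == "clean" && anyNA(values))
    stop("clean streams must not contain missing values")
  structure(as.numeric(values),
            signal_id = toupper(signal_id),
            sample_interval_s = sample_interval_s,
            start_time_s = start_time_s,
            provenance = provenance,
            class = "signal_stream")
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf("<signal_stream %s: %d samples @ %gs, %s, %.1f%% missing>\n",
              attr(x, "signal_id"), length(x), attr(x, "sample_interval_s"),
              attr(x, "provenance"), 100 * mean(is.na(x))))
  invisible(x)
}

stream_times <- function(stream) {
  attr(stream, "start_time_s") +
    (seq_along(stream) - 1L) * attr(stream, "sample_interval_s")
}

# rebuild a stream with new values but the same timing metadata
restamp_stream <- function(stream, values, provenance) {
  signal_stream(values, attr(stream, "signal_id"),
                attr(stream, "sample_interval_s"),
                attr(stream, "start_time_s"),
                provenance)
}
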