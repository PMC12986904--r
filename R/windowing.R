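#' Sliding-window plan
#'
#' Fixed-length overlapping windows: length \code{window_len_s} (T, default
#' 50 s), stride \code{stride_s} (S, default 10 s), sampling interval
#' \code{sample_interval_s} (default 1 s), giving N = T / interval samples
#' per window and 80\% overlap at the defaults.
#'
#' @param window_len_s window length T in seconds.
#' @param stride_s stride S in seconds, 0 < S <= T.
#' @param sample_interval_s sampling interval in seconds.
#' @return list of class \code{"window_plan"} with the derived
#'   \code{n_samples} (N) and \code{stride_samples}.
#' @export
window_plan <- function(window_len_s = 50, stride_s = 10,
                        sample_interval_s = 1) {
  if (stride_s <= 0 || stride_s > window_len_s)
    stop("require 0 < stride_s <= window_len_s")
  if (window_len_s %% sample_interval_s != 0)
    stop("window_len_s must be divisible by sample_interval_s")
  structure(list(window_len_s = window_len_s, stride_s = stride_s,
                 sample_interval_s = sample_interval_s,
                 n_samples = as.integer(window_len_s / sample_interval_s),
                 stride_samples = as.integer(stride_s / sample_interval_s)),
            class = "window_plan")
}

#' Number of complete sliding windows in a stream
#'
#' \code{floor((n_samples - N) / stride) + 1} when \code{n_samples >= N},
#' else 0; trailing samples that do not fill a final window are dropped.
#'
#' @param n_samples stream length in samples (>= 0).
#' @param plan a \code{\link{window_plan}}.
#' @return integer window count.
#' @export
#' @examples
#' count_windows(3600, window_plan())  # 356
count_windows <- function(n_samples, plan) {
  if (n_samples < 0) stop("n_samples must be >= 0")
  if (n_samples < plan$n_samples) return(0L)
  as.integer((n_samples - plan$n_samples) %/% plan$stride_samples + 1L)
}

#' Segment a stream into overlapping windows
#'
#' Window w (1-based) covers sample indices
#' \code{(w-1)*stride + 1 .. (w-1)*stride + N}; consecutive windows share
#' \code{N - stride} samples and a truncated trailing segment is excluded.
#'
#' @param stream a \code{\link{signal_stream}} (or numeric vector) of length
#'   >= N.
#' @param plan a \code{\link{window_plan}}.
#' @return list of windows; each is a list with \code{index} (1-based),
#'   \code{start_sample} (1-based index into the stream), \code{values}
#'   (length N, may contain NA) and \code{signal_id}.
#' @export
segment_stream <- function(stream, plan) {
  n <- length(stream)
  if (n < plan$n_samples)
    stop("stream shorter than one window (", n, " < ", plan$n_samples, ")")
  sid <- attr(stream, "signal_id")
  if (is.null(sid)) sid <- "X"
  k <- count_windows(n, plan)
  lapply(seq_len(k), function(w) {
    start <- (w - 1L) * plan$stride_samples + 1L
    list(index = w, start_sample = start,
         values = as.numeric(stream[start:(start + plan$n_samples - 1L)]),
         signal_id = sid)
  })
}
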