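# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards. The expression is forced in the calling frame.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# last-observation-carried-forward with backward fill for a leading gap;
# used for the "corrupted, gaps zero-order-filled" evaluation stage
locf_fill <- function(x) {
  n <- length(x)
  if (!anyNA(x)) return(x)
  last <- NA_real_
  for (i in seq_len(n)) {
    if (is.na(x[i])) x[i] <- last else last <- x[i]
  }
  if (is.na(x[1])) {
    first <- x[which(!is.na(x))[1]]
    i <- 1L
    while (i <= n && is.na(x[i])) { x[i] <- first; i <- i + 1L }
  }
  x
}

mse <- function(est, truth) mean((est - truth)^2)
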