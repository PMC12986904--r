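#' Clinical reference ranges for common vital signs
#'
#' Returns the table of clinically acceptable ranges \eqn{[L_j, U_j]} used
#' throughout the package for deviation scoring, soft-saturation modelling and
#' event definition, together with the derived quantities: clinical midpoint
#' \eqn{C = (L+U)/2}, clinical radius \eqn{R = (U-L)/2}, and the logistic
#' sensor-model parameters \eqn{b = C} and \eqn{a = (U-L)/(2\ln 19)} (so that
#' the bounds map to saturation levels \eqn{\sigma(\pm\ln 19) \approx
#' (0.05, 0.95)}).
#'
#' Default signals and ranges: SpO2 95--100 \%, heart rate (HR) 60--100 bpm,
#' respiratory rate (RR) 12--20 breaths/min, body temperature (TEMP)
#' 36.1--37.2 C, systolic BP (SYS) 90--120 mmHg, diastolic BP (DIA)
#' 60--80 mmHg, blood glucose (GLU) 70--140 mg/dL.
#'
#' @param signal_id optional character vector; restrict/reorder the table.
#' @param L,U optional numeric vectors overriding the bounds for
#'   \code{signal_id} (recycled against it).
#' @return A data.frame of class \code{"clinical_bounds"} with columns
#'   \code{signal_id}, \code{L}, \code{U}, \code{C}, \code{R}, \code{a},
#'   \code{b}.
#' @export
#' @examples
#' clinical_bounds()
#' clinical_bounds("HR")
clinical_bounds <- function(signal_id = NULL, L = NULL, U = NULL) {
  tab <- data.frame(
    signal_id = c("HR", "SPO2", "RR", "TEMP", "SYS", "DIA", "GLU"),
    L = c(60, 95, 12, 36.1, 90, 60, 70),
    U = c(100, 100, 20, 37.2, 120, 80, 140),
    stringsAsFactors = FALSE
  )
  if (!is.null(signal_id)) {
    signal_id <- toupper(signal_id)
    if (is.null(L)) {
      miss <- setdiff(signal_id, tab$signal_id)
      if (length(miss))
        stop("unknown signal_id: ", paste(miss, collapse = ", "))
      tab <- tab[match(signal_id, tab$signal_id), , drop = FALSE]
    } else {
      if (is.null(U)) stop("U must be given with L")
      tab <- data.frame(signal_id = signal_id, L = L, U = U,
                        stringsAsFactors = FALSE)
    }
  }
  if (any(tab$L >= tab$U)) stop("require L < U for every signal")
  tab$C <- (tab$L + tab$U) / 2
  tab$R <- (tab$U - tab$L) / 2
  lp <- derive_logistic_params(tab$L, tab$U)
  tab$a <- lp$a
  tab$b <- lp$b
  rownames(tab) <- tab$signal_id
  class(tab) <- c("clinical_bounds", "data.frame")
  tab
}

bounds_row <- function(bounds, signal_id) {
  i <- match(toupper(signal_id), bounds$signal_id)
  if (is.na(i)) stop("no clinical bounds for signal '", signal_id, "'")
  bounds[i, , drop = FALSE]
}

#' Logistic sensor-model parameters from clinical bounds
#'
#' The bounded logistic measurement model places its midpoint at the clinical
#' midpoint, \eqn{b = (L+U)/2}, and chooses the slope scale \eqn{a} so that the
#' clinical bounds correspond to the 5\% / 95\% saturation levels of the
#' logistic curve: \eqn{a = (U-L)/(2 \ln 19)} (since \eqn{\sigma(\ln 19) =
#' 0.95}).
#'
#' @param L,U numeric lower/upper clinical bounds, \code{L < U}. Vectorised.
#' @return list with components \code{a} and \code{b}.
#' @export
#' @examples
#' derive_logistic_params(60, 100)  # b = 80, a = 40 / (2 log(19))
derive_logistic_params <- function(L, U) {
  if (any(L >= U)) stop("require L < U")
  list(a = (U - L) / (2 * log(19)), b = (L + U) / 2)
}

#' Bounded logistic measurement function
#'
#' Maps a latent physiological level \code{s} into the clinical range through
#' \eqn{h(s) = L + (U-L)\,\sigma((s-b)/a)}, where \eqn{\sigma} is the standard
#' logistic function. \code{h} is strictly increasing with range \eqn{(L, U)},
#' approximately linear near the midpoint and saturating near the bounds --
#' emulating soft sensor clipping.
#'
#' @param s numeric latent level(s).
#' @param bounds one row of \code{\link{clinical_bounds}} (or any list with
#'   elements \code{L}, \code{U}, \code{a}, \code{b}).
#' @return numeric, same length as \code{s}.
#' @export
logistic_measure <- function(s, bounds) {
  u <- (s - bounds$b) / bounds$a
  bounds$L + (bounds$U - bounds$L) * stats::plogis(u)
}

#' Derivative of the bounded logistic measurement function
#'
#' \eqn{dh/ds = (U-L)/a \cdot \sigma(u)(1-\sigma(u))} with
#' \eqn{u = (s-b)/a}. At the midpoint this equals \eqn{(U-L)/(4a) =
#' \ln(19)/2 \approx 1.472} for the default parameterisation, independent of
#' the bounds.
#'
#' @inheritParams logistic_measure
#' @return numeric, same length as \code{s}.
#' @export
measurement_jacobian <- function(s, bounds) {
  u <- (s - bounds$b) / bounds$a
  sig <- stats::plogis(u)
  (bounds$U - bounds$L) / bounds$a * sig * (1 - sig)
}

# inverse of logistic_measure, with clamping away from the asymptotes so the
# logit stays finite; used to initialise the EKF latent state
inverse_logistic_measure <- function(z, bounds, margin = 0.01) {
  span <- bounds$U - bounds$L
  z <- pmin(pmax(z, bounds$L + margin * span), bounds$U - margin * span)
  p <- (z - bounds$L) / span
  bounds$b + bounds$a * stats::qlogis(p)
}
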