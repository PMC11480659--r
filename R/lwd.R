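#' LWD1 Fourier-series forcing
#'
#' The clock input LWD1 has no modelled upstream regulator; its abundance is
#' imposed as a second-order Fourier series
#' \deqn{W(t) = a_1 \sin(2\pi t/T) + b_1 \cos(2\pi t/T)
#'             + a_2 \sin(4\pi t/T) + b_2 \cos(4\pi t/T) + c_0,}
#' with fundamental period \eqn{T}. Under entrained photoperiods the period
#' defaults to the 24 h cycle; under constant light the fitted period is
#' 26 h (see [lwd_forcing_24l()]).
#'
#' @param a1,b1,a2,b2 Harmonic coefficients (series units).
#' @param c0 Offset; equals the mean of the series over one period.
#' @param fundamental_period_h Fundamental period in hours (> 0).
#' @return An object of class `lwd_forcing`.
#' @seealso [lwd_value()]
#' @export
lwd_forcing <- function(a1, b1, a2, b2, c0, fundamental_period_h = 24) {
  if (!is.finite(fundamental_period_h) || fundamental_period_h <= 0)
    stop("fundamental_period_h must be positive", call. = FALSE)
  coefs <- c(a1 = a1, b1 = b1, a2 = a2, b2 = b2, c0 = c0)
  if (any(!is.finite(coefs))) stop("coefficients must be finite", call. = FALSE)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, c0 = c0,
                 fundamental_period_h = fundamental_period_h),
            class = "lwd_forcing")
}

#' Constant-light LWD1 forcing fitted from 24L expression data
#'
#' The coefficient set reported for LWD1 under constant light:
#' \eqn{0.45 \sin(2\pi t/26) + 0.4 \cos(2\pi t/26) + 0.48 \sin(4\pi t/26)
#' + 0.1 \cos(4\pi t/26) + 1.52}.
#'
#' @param fundamental_period_h Fundamental period; 26 h for the constant
#'   light fit, 24 h when the same waveform is used under entrained cycles.
#' @return An `lwd_forcing` object.
#' @export
lwd_forcing_24l <- function(fundamental_period_h = 26) {
  lwd_forcing(a1 = 0.45, b1 = 0.4, a2 = 0.48, b2 = 0.1, c0 = 1.52,
              fundamental_period_h = fundamental_period_h)
}

#' Evaluate an LWD1 forcing series
#'
#' @param forcing An [lwd_forcing()] object.
#' @param t Time(s) in hours; vectorised.
#' @return LWD1 abundance at `t` (same units as the fitted series).
#' @examples
#' lwd_value(lwd_forcing_24l(), 0)   # 0.4 + 0.1 + 1.52 = 2.02
#' @export
lwd_value <- function(forcing, t) {
  stopifnot(inherits(forcing, "lwd_forcing"))
  if (any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  w <- 2 * pi * t / forcing$fundamental_period_h
  forcing$a1 * sin(w) + forcing$b1 * cos(w) +
    forcing$a2 * sin(2 * w) + forcing$b2 * cos(2 * w) + forcing$c0
}

#' @export
print.lwd_forcing <- function(x, ...) {
  cat(sprintf(
    "LWD1 Fourier forcing: T = %g h, a1 = %g, b1 = %g, a2 = %g, b2 = %g, c0 = %g\n",
    x$fundamental_period_h, x$a1, x$b1, x$a2, x$b2, x$c0))
  invisible(x)
}
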