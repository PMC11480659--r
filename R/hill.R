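#' Hill regulation factors
#'
#' Saturating regulatory response functions with Hill exponent 2, the two
#' forms used throughout the clock network: a decreasing (repressing) factor
#' `1 / (1 + (x/K)^2)` and an increasing (activating) factor
#' `(x/K)^2 / (1 + (x/K)^2)`. For any abundance `x >= 0` and half-saturation
#' `K > 0` the two forms sum exactly to 1.
#'
#' @param x Regulator abundance (non-negative, arbitrary relative units).
#'   Vectorised.
#' @param K Half-saturation constant (strictly positive).
#' @return A factor in `(0, 1]` (`hill_repress`) or `[0, 1)` (`hill_activate`).
#' @examples
#' hill_repress(0, 1)            # 1: no repressor present
#' hill_activate(1, 1)           # 0.5: half-saturation
#' hill_activate(2, 1) + hill_repress(2, 1)  # exactly 1
#' @export
hill_repress <- function(x, K) {
  check_hill_args(x, K)
  1 / (1 + (x / K)^2)
}

#' @rdname hill_repress
#' @export
hill_activate <- function(x, K) {
  check_hill_args(x, K)
  r <- (x / K)^2
  r / (1 + r)
}

check_hill_args <- function(x, K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("Hill half-saturation constant K must be strictly positive", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("regulator abundance x must be finite and non-negative", call. = FALSE)
  invisible(NULL)
}
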