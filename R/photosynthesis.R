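#' Algebraic photosynthetic-parameter model
#'
#' Maps the clock state to a photosynthetic parameter through the saturating
#' relation
#' \deqn{P_i = \alpha_i + \frac{[CL]^2}{K_{i1}^2 + [CL]^2}
#'       + \sum_{j=1}^{3} \frac{[X_j]^2}{H_{ij}^2 + [X_j]^2},}
#' where \eqn{[CL]} is the CCA1/LHY protein level, \eqn{[X_j]} are the
#' Lhcb1, RbcS1 and atpA transcript levels, \eqn{\alpha_i} the basal level
#' of parameter \eqn{i \in \{P_n, G_s, C_i, T_r\}} in its measured unit,
#' \eqn{K_{i1}} the CL activation half-saturation and \eqn{H_{ij}} the
#' facilitation half-saturations. Every value lies in
#' \eqn{[\alpha_i, \alpha_i + 4]} and the map is non-decreasing in each
#' input.
#'
#' @param CL CCA1/LHY abundance (>= 0); vectorised.
#' @param X Numeric vector (or 3-column matrix, one row per time) of the
#'   three transcript abundances (Lhcb1, RbcS1, atpA).
#' @param params_i Named numeric vector `c(alpha, K1, H1, H2, H3)` — one
#'   parameter's slice of [default_output_params()], with or without the
#'   `"<param>."` prefix.
#' @return Photosynthetic-parameter value(s), same length as `CL`.
#' @examples
#' photosynthetic_rate(0, c(0, 0, 0), c(alpha = 1.2, K1 = 1, H1 = 1, H2 = 1, H3 = 1))
#' @export
photosynthetic_rate <- function(CL, X, params_i) {
  p <- strip_output_prefix(params_i)
  if (any(p[c("K1", "H1", "H2", "H3")] <= 0))
    stop("half-saturation constants K1, H1..H3 must be > 0", call. = FALSE)
  if (is.null(dim(X))) X <- matrix(X, ncol = 3, nrow = length(CL), byrow = TRUE)
  if (any(CL < 0) || any(X < 0))
    stop("abundances must be non-negative", call. = FALSE)
  p[["alpha"]] + hill_activate(CL, p[["K1"]]) +
    hill_activate(X[, 1], p[["H1"]]) +
    hill_activate(X[, 2], p[["H2"]]) +
    hill_activate(X[, 3], p[["H3"]])
}

strip_output_prefix <- function(params_i) {
  nm <- sub("^[A-Za-z]+\\.", "", names(params_i))
  req <- c("alpha", "K1", "H1", "H2", "H3")
  if (!all(req %in% nm))
    stop("params_i must carry alpha, K1, H1, H2, H3", call. = FALSE)
  stats::setNames(as.numeric(params_i), nm)[req]
}

#' Photosynthetic-parameter time courses from a trajectory
#'
#' Applies [photosynthetic_rate()] pointwise along a simulated trajectory to
#' produce the four measured photosynthetic parameter series: net
#' photosynthetic rate Pn, stomatal conductance Gs, intercellular CO2
#' concentration Ci and transpiration rate Tr. The map is memoryless, so the
#' output grid is exactly the input grid.
#'
#' @param traj A `clock_trajectory` (or a data frame with columns `time_h`,
#'   `CL`, `M_Lhcb1`, `M_RbcS1`, `M_atpA`, e.g. from
#'   [sample_like_experiment()]).
#' @param output_params The 20 output-map constants
#'   ([default_output_params()] layout).
#' @return Named list of four data frames (`Pn`, `Gs`, `Ci`, `Tr`), each
#'   with columns `time_h`, `value`.
#' @export
simulate_photoparams <- function(traj, output_params = default_output_params()) {
  df <- if (inherits(traj, "clock_trajectory")) as.data.frame(traj) else traj
  req <- c("time_h", "CL", "M_Lhcb1", "M_RbcS1", "M_atpA")
  if (!all(req %in% names(df)))
    stop("trajectory must carry CL and the three photosynthetic transcripts",
         call. = FALSE)
  X <- as.matrix(df[, c("M_Lhcb1", "M_RbcS1", "M_atpA")])
  out <- lapply(c("Pn", "Gs", "Ci", "Tr"), function(i) {
    slice <- output_params[paste0(i, ".", c("alpha", "K1", "H1", "H2", "H3"))]
    data.frame(time_h = df$time_h,
               value = photosynthetic_rate(df$CL, X, slice))
  })
  names(out) <- c("Pn", "Gs", "Ci", "Tr")
  out
}
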