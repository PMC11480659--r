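#' Time derivatives of the nine-variable clock oscillator
#'
#' The core oscillator is a transcription-translation feedback loop over four
#' merged transcript/protein pairs (MCL/CL for CCA1/LHY, MP97/P97 for
#' PRR9/PRR7, MP51/P51 for PRR5/TOC1, MEL/EL for ELF4/LUX) plus the activated
#' fraction P of a photosensitive protein. Transcription is shaped by squared
#' Hill factors on the regulatory edges (P97 and P51 repress MCL; CL activates
#' MP97 and represses MP51 and MEL; EL represses MP97 and MP51; P51 represses
#' MEL), an acute light term proportional to \eqn{L(t) P} on MCL and MP97
#' (the dawn response), and LWD1 activation of the CCA1, PRR9 and TOC1 genes
#' through an increasing Hill factor of the Fourier forcing. Translation and
#' degradation follow mass action; MCL turnover is light-dependent. P obeys
#' \eqn{dP/dt = p_{on}(1-P)D(t) - p_{off} P L(t)}: it accumulates in darkness
#' and is consumed by light.
#'
#' @param state Named numeric vector with the nine clock components (see
#'   [clock_state_names()]); abundances must be non-negative.
#' @param t Time in hours since ZT0.
#' @param params Clock parameters ([default_clock_params()] layout).
#' @param schedule A [build_schedule()] photoperiod.
#' @param lwd An [lwd_forcing()] object.
#' @return Named numeric vector of nine time derivatives.
#' @export
clock_derivatives <- function(state, t, params = default_clock_params(),
                              schedule = build_schedule("12L12D"),
                              lwd = lwd_forcing_24l(24)) {
  if (any(state[clock_state_names()] < 0))
    stop("clock state must be non-negative", call. = FALSE)
  L <- light_at(schedule, t)
  d <- clock_rhs(state, L, lwd_value(lwd, t), as.list(params))
  names(d) <- clock_state_names()
  d
}

## Right-hand side shared by the exported wrappers and the integrator.
## `s` is a named vector (or larger vector containing the clock names),
## `L` is 0/1, `W` the LWD1 abundance, `p` a list of parameters.
clock_rhs <- function(s, L, W, p) {
  D <- 1 - L
  actW <- (W / p$K_lwd)^2 / (1 + (W / p$K_lwd)^2)
  hr <- function(x, K) 1 / (1 + (x / K)^2)
  ha <- function(x, K) { r <- (x / K)^2; r / (1 + r) }

  dMCL <- p$v_mcl * hr(s[["P97"]], p$K_p97_mcl) * hr(s[["P51"]], p$K_p51_mcl) +
    p$q_light * L * s[["P"]] + p$a_lwd_mcl * actW -
    (p$d_mcl_l * L + p$d_mcl_d * D) * s[["MCL"]]
  dCL <- p$k_tl * s[["MCL"]] - p$d_cl * s[["CL"]]

  dMP97 <- p$v_mp97 * ha(s[["CL"]], p$K_cl_mp97) * hr(s[["EL"]], p$K_el) +
    p$q_light * L * s[["P"]] + p$a_lwd_prr * actW - p$d_mrna * s[["MP97"]]
  dP97 <- p$k_tl * s[["MP97"]] - p$d_p97 * s[["P97"]]

  dMP51 <- p$v_mp51 * hr(s[["CL"]], p$K_cl_rep) * hr(s[["EL"]], p$K_el) +
    p$a_lwd_prr * actW - p$d_mrna * s[["MP51"]]
  dP51 <- p$k_tl * s[["MP51"]] - p$d_p51 * s[["P51"]]

  dMEL <- p$v_mel * hr(s[["CL"]], p$K_cl_rep) * hr(s[["P51"]], p$K_p51_mel) -
    p$d_mrna * s[["MEL"]]
  dEL <- p$k_tl * s[["MEL"]] - p$d_el * s[["EL"]]

  dP <- p$p_on * (1 - s[["P"]]) * D - p$p_off * s[["P"]] * L

  c(dMCL, dCL, dMP97, dP97, dMP51, dP51, dMEL, dEL, dP)
}

#' Time derivatives of the photosynthetic gene variables
#'
#' Six output variables (transcript/protein pairs for Lhcb1, RbcS1, atpA)
#' driven by the core clock through CL: Lhcb1 transcription is CL-activated
#' with an additional direct light term (day peak), RbcS1 and atpA are
#' CL-repressed (night peaks). Translation and degradation are mass action.
#'
#' @param state Named vector with the six photogene components
#'   ([photogene_state_names()]).
#' @param clock Named vector with the clock components (only CL is read).
#' @param t Time in hours.
#' @param params Photogene parameters ([default_photogene_params()] layout).
#' @param schedule Photoperiod schedule supplying \eqn{L(t)}.
#' @return Named numeric vector of six time derivatives.
#' @export
photogene_derivatives <- function(state, clock, t,
                                  params = default_photogene_params(),
                                  schedule = build_schedule("12L12D")) {
  if (any(state[photogene_state_names()] < 0) || clock[["CL"]] < 0)
    stop("states must be non-negative", call. = FALSE)
  L <- light_at(schedule, t)
  d <- photogene_rhs(state, clock[["CL"]], L, as.list(params))
  names(d) <- photogene_state_names()
  d
}

photogene_rhs <- function(s, CL, L, p) {
  hr <- function(x, K) 1 / (1 + (x / K)^2)
  ha <- function(x, K) { r <- (x / K)^2; r / (1 + r) }
  dMLb <- p$v_lhcb1 * ha(CL, p$K_cl_lhcb1) + p$q_lhcb1 * L -
    p$d_m_lhcb1 * s[["M_Lhcb1"]]
  dPLb <- p$k_out * s[["M_Lhcb1"]] - p$d_pout * s[["P_Lhcb1"]]
  dMRb <- p$v_rbcs1 * hr(CL, p$K_cl_rbcs1) - p$d_m_rbcs1 * s[["M_RbcS1"]]
  dPRb <- p$k_out * s[["M_RbcS1"]] - p$d_pout * s[["P_RbcS1"]]
  dMat <- p$v_atpa * hr(CL, p$K_cl_atpa) - p$d_m_atpa * s[["M_atpA"]]
  dPat <- p$k_out * s[["M_atpA"]] - p$d_pout * s[["P_atpA"]]
  c(dMLb, dPLb, dMRb, dPRb, dMat, dPat)
}

## Full 15-variable right-hand side used by the integrator.
model_rhs <- function(s, L, W, p) {
  c(clock_rhs(s, L, W, p), photogene_rhs(s, s[["CL"]], L, p))
}

#' Construct the clock-controlled photosynthesis model
#'
#' Bundles a parameter set, a photoperiod schedule and an LWD1 forcing into a
#' model object that [simulate.clock_model()] integrates. When `lwd` is left
#' `NULL` the forcing follows the experimental convention: the printed
#' constant-light coefficient set, with fundamental period 26 h under `24L`
#' and the schedule cycle length under entrained photoperiods.
#'
#' @param params Full 56-parameter named vector (validated).
#' @param schedule Preset name or [build_schedule()] object (default
#'   `"12L12D"`).
#' @param lwd Optional [lwd_forcing()] override.
#' @return An object of class `clock_model`.
#' @examples
#' m <- clock_model(schedule = "24L")
#' m
#' @export
clock_model <- function(params = default_params(), schedule = "12L12D",
                        lwd = NULL) {
  validate_params(params)
  params <- params[names(default_params())]
  if (!inherits(schedule, "photoperiod_schedule"))
    schedule <- build_schedule(schedule)
  if (is.null(lwd)) {
    period <- if (duty_cycle(schedule) >= 1) 26 else schedule$cycle_h
    lwd <- lwd_forcing_24l(fundamental_period_h = period)
  }
  stopifnot(inherits(lwd, "lwd_forcing"))
  structure(list(params = params, schedule = schedule, lwd = lwd),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Clock-controlled photosynthesis model\n")
  cat(sprintf("  %d state variables, %d parameters\n",
              length(model_state_names()), length(x$params)))
  cat(sprintf("  photoperiod: %s (light fraction %.3g)\n",
              x$schedule$name, duty_cycle(x$schedule)))
  cat(sprintf("  LWD1 forcing period: %g h\n", x$lwd$fundamental_period_h))
  invisible(x)
}

#' @export
coef.clock_model <- function(object, ...) object$params
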