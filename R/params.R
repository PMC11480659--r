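## Parameter bookkeeping: the full model exposes exactly 56 named parameters,
## split as 24 core-clock kinetic constants, 12 photosynthetic-gene kinetic
## constants, and 20 algebraic output-map constants (4 photosynthetic
## parameters x (alpha, K, H1..H3)).

#' Names of the model state variables and parameters
#'
#' The model carries 15 state variables: nine clock variables (four
#' transcript/protein pairs MCL/CL, MP97/P97, MP51/P51, MEL/EL for the merged
#' components CCA1/LHY, PRR9/PRR7, PRR5/TOC1, ELF4/LUX, plus the activated
#' fraction P of the photosensitive protein) and six photosynthetic output
#' variables (transcript/protein pairs for Lhcb1, RbcS1 and atpA).
#'
#' @return Character vectors of names.
#' @export
clock_state_names <- function() {
  c("MCL", "CL", "MP97", "P97", "MP51", "P51", "MEL", "EL", "P")
}

#' @rdname clock_state_names
#' @export
photogene_state_names <- function() {
  c("M_Lhcb1", "P_Lhcb1", "M_RbcS1", "P_RbcS1", "M_atpA", "P_atpA")
}

#' @rdname clock_state_names
#' @export
model_state_names <- function() c(clock_state_names(), photogene_state_names())

#' Basal kinetic parameters of the core clock
#'
#' The 24 named rate and Hill constants of the nine-variable oscillator:
#' maximal transcription rates (`v_*`, 1/h in relative-abundance units),
#' Hill half-saturations for the regulatory edges (`K_*`), a shared acute
#' light-activation coefficient `q_light` acting on MCL and MP97 via
#' \eqn{L(t) P}, LWD1 coupling amplitudes (`a_lwd_mcl` for the CCA1 edge,
#' `a_lwd_prr` shared by the PRR9 and TOC1 edges) with a shared
#' half-saturation `K_lwd`, transcript degradation rates (separate
#' light/dark rates for MCL, one shared rate `d_mrna` for the other three
#' transcripts), one shared translation rate `k_tl`, per-protein degradation
#' rates (the stage turnover times place the oscillator's resonant mode
#' near the ~26 h free-running response), and the on/off rates of the
#' photosensitive protein P.
#'
#' Values are the packaged basal parameter set, calibrated once against the
#' 12L12D phase anchors (CL peak at dawn, P97 at ZT6-9, P51 at dusk, EL at
#' ZT12-15) and the constant-light period/phase-delay behaviour, then
#' frozen.
#'
#' @return Named numeric vector of 24 positive constants.
#' @export
default_clock_params <- function() {
  c(
    ## maximal transcription rates (1/h)
    v_mcl  = 2.50,
    v_mp97 = 2.20,
    v_mp51 = 2.50,
    v_mel  = 2.50,
    ## Hill half-saturations of regulatory edges
    K_p97_mcl  = 1.50,   # P97 -| MCL
    K_p51_mcl  = 0.50,   # P51 -| MCL
    K_cl_mp97  = 0.35,   # CL  -> MP97 (activation)
    K_cl_rep   = 0.50,   # CL  -| MP51 and CL -| MEL (shared)
    K_el       = 1.30,   # EL  -| MP97 and EL -| MP51 (shared)
    K_p51_mel  = 2.50,   # P51 -| MEL
    ## acute light activation via L(t) * P (shared MCL/MP97 coefficient)
    q_light = 3.00,
    ## LWD1 positive-loop coupling
    a_lwd_mcl = 0.55,
    a_lwd_prr = 0.15,
    K_lwd     = 1.50,
    ## transcript degradation (1/h); MCL is dark-stabilized
    d_mcl_l = 0.70,
    d_mcl_d = 0.45,
    d_mrna  = 0.54,
    ## protein kinetics
    k_tl  = 0.54,
    d_cl  = 0.54,
    d_p97 = 0.45,
    d_p51 = 0.45,
    d_el  = 0.54,
    ## photosensitive protein P (accumulates in darkness, consumed by light)
    p_on  = 0.30,
    p_off = 2.50
  )
}

#' Basal kinetic parameters of the photosynthetic genes
#'
#' The 12 named constants of the six output ODEs: per-gene maximal
#' transcription rates and CL half-saturations (Lhcb1 is CL-activated with an
#' additional direct light term `q_lhcb1`; RbcS1 and atpA are CL-repressed,
#' giving their night peaks), per-gene transcript degradation rates, and one
#' shared translation and protein degradation rate.
#'
#' @return Named numeric vector of 12 positive constants.
#' @export
default_photogene_params <- function() {
  c(
    v_lhcb1 = 1.50, K_cl_lhcb1 = 0.80, q_lhcb1 = 0.40, d_m_lhcb1 = 0.55,
    v_rbcs1 = 1.20, K_cl_rbcs1 = 0.60, d_m_rbcs1 = 0.45,
    v_atpa  = 1.10, K_cl_atpa  = 0.60, d_m_atpa  = 0.45,
    k_out = 0.40, d_pout = 0.30
  )
}

#' Basal parameters of the algebraic photosynthetic-parameter map
#'
#' The 20 constants of the saturating map
#' \eqn{P_i = \alpha_i + [CL]^2/(K_{i1}^2 + [CL]^2) +
#' \sum_j [X_j]^2/(H_{ij}^2 + [X_j]^2)} for
#' \eqn{i \in \{P_n, G_s, C_i, T_r\}} and \eqn{X_j} the Lhcb1, RbcS1, atpA
#' transcripts: a basal level `alpha` in the measured unit of parameter `i`
#' (e.g. umol m-2 s-1 for Pn), the CL half-saturation `K1`, and the three
#' facilitation half-saturations `H1..H3`.
#'
#' @return Named numeric vector of 20 constants
#'   (`<param>.alpha`, `<param>.K1`, `<param>.H1`, `<param>.H2`, `<param>.H3`).
#' @export
default_output_params <- function() {
  c(
    Pn.alpha = 1.20, Pn.K1 = 1.00, Pn.H1 = 1.20, Pn.H2 = 2.00, Pn.H3 = 2.00,
    Gs.alpha = 0.04, Gs.K1 = 1.00, Gs.H1 = 1.50, Gs.H2 = 1.20, Gs.H3 = 1.20,
    Ci.alpha = 250,  Ci.K1 = 0.80, Ci.H1 = 1.80, Ci.H2 = 1.20, Ci.H3 = 1.20,
    Tr.alpha = 0.50, Tr.K1 = 1.00, Tr.H1 = 1.30, Tr.H2 = 2.20, Tr.H3 = 2.20
  )
}

#' The packaged basal parameter set
#'
#' Concatenates the clock, photosynthetic-gene and output-map parameters into
#' the full 56-parameter basal set.
#'
#' @return Named numeric vector of length 56.
#' @export
default_params <- function() {
  c(default_clock_params(), default_photogene_params(), default_output_params())
}

#' Validate a full parameter set
#'
#' Checks that a parameter vector carries exactly the 56 expected names and
#' that every rate, Hill and half-saturation constant is strictly positive
#' (basal levels `*.alpha` may be zero).
#'
#' @param params Named numeric vector.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  expected <- names(default_params())
  if (is.null(names(params)) || !setequal(names(params), expected) ||
      length(params) != length(expected))
    stop("parameter set must carry exactly the ", length(expected),
         " named model parameters", call. = FALSE)
  params <- params[expected]
  if (any(!is.finite(params))) stop("parameters must be finite", call. = FALSE)
  alpha <- grepl("\\.alpha$", names(params))
  if (any(params[!alpha] <= 0))
    stop("all rate and half-saturation constants must be > 0", call. = FALSE)
  if (any(params[alpha] < 0))
    stop("basal levels alpha must be >= 0", call. = FALSE)
  invisible(params)
}
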