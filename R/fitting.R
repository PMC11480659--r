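#' Fit a second-order Fourier series at fixed period
#'
#' Linear least-squares fit of
#' \eqn{a_1 \sin(2\pi t/T) + b_1 \cos(2\pi t/T) + a_2 \sin(4\pi t/T) +
#' b_2 \cos(4\pi t/T) + c_0} to a sampled series, with the fundamental
#' period \eqn{T} imposed (the constant-light LWD1 fit hard-codes
#' \eqn{T = 26} h). The reported `mse` is the sum of squared residuals, the
#' same convention as [mse()].
#'
#' @param series Data frame with columns `time_h`, `value`; at least 6
#'   distinct time points.
#' @param fundamental_period_h Imposed fundamental period (> 0).
#' @return An object of class `fourier_fit` with elements `forcing` (an
#'   [lwd_forcing()]), `mse`, `n` and the underlying `series`.
#' @examples
#' tt <- seq(0, 24, by = 3)
#' y <- lwd_value(lwd_forcing_24l(), tt)
#' fit <- fit_fourier(data.frame(time_h = tt, value = y), 26)
#' coef(fit)
#' @export
fit_fourier <- function(series, fundamental_period_h) {
  series <- check_series(series)
  if (!is.finite(fundamental_period_h) || fundamental_period_h <= 0)
    stop("fundamental_period_h must be positive", call. = FALSE)
  if (length(unique(series$time_h)) < 6)
    stop("need at least 6 distinct time points", call. = FALSE)
  w <- 2 * pi * series$time_h / fundamental_period_h
  X <- cbind(s1 = sin(w), c1 = cos(w), s2 = sin(2 * w), c2 = cos(2 * w))
  fit <- stats::lm(series$value ~ X)
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("rank-deficient design: sampling grid aliases the harmonics",
         call. = FALSE)
  forcing <- lwd_forcing(a1 = unname(cf["Xs1"]), b1 = unname(cf["Xc1"]),
                         a2 = unname(cf["Xs2"]), b2 = unname(cf["Xc2"]),
                         c0 = unname(cf["(Intercept)"]),
                         fundamental_period_h = fundamental_period_h)
  structure(list(forcing = forcing, mse = sum(stats::residuals(fit)^2),
                 n = nrow(series), series = series),
            class = "fourier_fit")
}

#' @export
coef.fourier_fit <- function(object, ...) {
  f <- object$forcing
  c(a1 = f$a1, b1 = f$b1, a2 = f$a2, b2 = f$b2, c0 = f$c0)
}

#' @export
fitted.fourier_fit <- function(object, ...) {
  lwd_value(object$forcing, object$series$time_h)
}

#' @export
residuals.fourier_fit <- function(object, ...) {
  object$series$value - fitted(object)
}

#' @export
predict.fourier_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$series$time_h else newdata$time_h
  lwd_value(object$forcing, tt)
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf("Second-order Fourier fit (T = %g h, n = %d, SSE = %.4g)\n",
              x$forcing$fundamental_period_h, x$n, x$mse))
  print(round(coef(x), 4))
  invisible(x)
}

#' Estimate the photosynthetic output-map parameters
#'
#' Cost-minimising estimation of the 20 algebraic output constants
#' (\eqn{\alpha_i, K_{i1}, H_{i1..3}} for each of Pn, Gs, Ci, Tr) from
#' photosynthetic-parameter time courses measured under constant light, with
#' every kinetic parameter of the clock and photosynthetic genes held fixed.
#' The clock is simulated once under the training photoperiod (after 12L12D
#' entrainment); the objective for each output is the summed squared error
#' between [photosynthetic_rate()] applied to that trajectory and the
#' observations. Each output's five parameters are estimated independently
#' by bounded quasi-Newton (`L-BFGS-B`) local searches from `n_starts`
#' Latin-hypercube start points (half-saturations sampled on a log scale);
#' the best converged start wins. The procedure is deterministic given
#' (`obs`, bounds, `seed`, `n_starts`).
#'
#' @param obs Named list of observed series (data frames `time_h`, `value`)
#'   for some or all of `Pn`, `Gs`, `Ci`, `Tr`.
#' @param params Full 56-parameter vector; only the 36 kinetic entries are
#'   used (frozen), the output entries are ignored.
#' @param schedule Training photoperiod (default `"24L"`, the control group
#'   of the study design).
#' @param n_starts Multi-start count (default 20).
#' @param seed Integer seed for the Latin-hypercube start points.
#' @param lower,upper Optional named bounds on `c(alpha, K1, H1, H2, H3)`;
#'   defaults: `alpha` in `[0, max(obs)]`, half-saturations in
#'   `[0.02, 20]`.
#' @param entrain_days,dt Protocol controls passed to
#'   [entrain_then_switch()].
#' @return An object of class `photofit` with elements `parameters` (named
#'   20-vector, possibly a subset if `obs` omits outputs), `cost` (total
#'   SSE), `per_output` (per-output SSE), `n_starts`, `seed`, `converged`.
#' @export
fit_output_params <- function(obs, params = default_params(),
                              schedule = "24L", n_starts = 20, seed = 1,
                              lower = NULL, upper = NULL,
                              entrain_days = 7, dt = 0.05) {
  outputs <- intersect(c("Pn", "Gs", "Ci", "Tr"), names(obs))
  if (length(outputs) == 0)
    stop("obs must contain at least one of Pn, Gs, Ci, Tr", call. = FALSE)
  validate_params(params)
  obs <- lapply(obs, check_series)

  tmax <- max(vapply(obs[outputs], function(s) max(s$time_h), numeric(1)))
  traj <- entrain_then_switch(params, target = schedule,
                              entrain_days = entrain_days,
                              post_days = ceiling(tmax / 24 + 1e-9), dt = dt)
  df <- as.data.frame(traj)

  fitted_pars <- numeric(0)
  per_output <- numeric(0)
  converged <- TRUE
  for (i in outputs) {
    s <- obs[[i]]
    idx <- match(round(s$time_h / dt), round(df$time_h / dt))
    if (any(is.na(idx)))
      stop("observation times for ", i,
           " do not align with the integration grid", call. = FALSE)
    CL <- df$CL[idx]
    X <- as.matrix(df[idx, c("M_Lhcb1", "M_RbcS1", "M_atpA")])
    y <- s$value

    lo <- c(alpha = 0, K1 = 0.02, H1 = 0.02, H2 = 0.02, H3 = 0.02)
    hi <- c(alpha = max(y), K1 = 20, H1 = 20, H2 = 20, H3 = 20)
    if (!is.null(lower)) lo[names(lower)] <- lower
    if (!is.null(upper)) hi[names(upper)] <- upper
    if (any(hi <= lo)) stop("upper bounds must exceed lower bounds",
                            call. = FALSE)

    objective <- function(theta) {
      ## theta: alpha on natural scale, half-saturations on log scale
      p <- c(theta[1], exp(theta[-1]))
      names(p) <- c("alpha", "K1", "H1", "H2", "H3")
      sum((photosynthetic_rate(CL, X, p) - y)^2)
    }
    t_lo <- c(lo[1], log(lo[-1])); t_hi <- c(hi[1], log(hi[-1]))
    set.seed(seed + match(i, c("Pn", "Gs", "Ci", "Tr")))
    starts <- lhs::randomLHS(n_starts, 5)
    best <- NULL
    any_conv <- FALSE
    for (k in seq_len(n_starts)) {
      th0 <- t_lo + starts[k, ] * (t_hi - t_lo)
      res <- tryCatch(
        stats::optim(th0, objective, method = "L-BFGS-B",
                     lower = t_lo, upper = t_hi,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (res$convergence == 0) any_conv <- TRUE
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best))
      stop("all optimisation starts failed for output ", i, call. = FALSE)
    converged <- converged && any_conv
    est <- c(best$par[1], exp(best$par[-1]))
    names(est) <- paste0(i, ".", c("alpha", "K1", "H1", "H2", "H3"))
    fitted_pars <- c(fitted_pars, est)
    per_output[i] <- best$value
  }

  structure(list(parameters = fitted_pars, cost = sum(per_output),
                 per_output = per_output, n_starts = n_starts, seed = seed,
                 converged = converged, schedule = schedule,
                 kinetic_params = params[c(names(default_clock_params()),
                                           names(default_photogene_params()))],
                 obs = obs[outputs], entrain_days = entrain_days, dt = dt),
            class = "photofit")
}

#' @export
coef.photofit <- function(object, ...) object$parameters

#' @export
print.photofit <- function(x, ...) {
  cat(sprintf(
    "Photosynthetic output fit under %s: %d parameters, SSE = %.4g (%s)\n",
    x$schedule, length(x$parameters), x$cost,
    if (x$converged) "converged" else "not converged"))
  print(round(x$parameters, 4))
  invisible(x)
}

#' @export
summary.photofit <- function(object, ...) {
  cat(sprintf("Multi-start output-parameter fit (%d starts, seed %d)\n",
              object$n_starts, object$seed))
  print(object)
  cat("Per-output SSE:\n")
  print(round(object$per_output, 4))
  invisible(object)
}

#' Predict photosynthetic-parameter curves from a fit
#'
#' Re-simulates the clock under a photoperiod (default the training
#' schedule) and applies the fitted output map.
#'
#' @param object A `photofit`.
#' @param schedule Target photoperiod.
#' @param post_days Days simulated after the switch.
#' @param ... Ignored.
#' @return Named list of predicted series (see [simulate_photoparams()]).
#' @export
predict.photofit <- function(object, schedule = object$schedule,
                             post_days = 2, ...) {
  full <- default_params()
  full[names(object$kinetic_params)] <- object$kinetic_params
  full[names(object$parameters)] <- object$parameters
  traj <- entrain_then_switch(full, target = schedule,
                              entrain_days = object$entrain_days,
                              post_days = post_days, dt = object$dt)
  simulate_photoparams(traj, full[names(default_output_params())])
}

#' Predict clock and output dynamics under several photoperiods
#'
#' Runs the entrain-then-switch protocol for each schedule with one shared
#' parameter set: only the light input (and its LWD1 forcing convention)
#' changes between runs, which is how held-out photoperiods are predicted
#' from the basal set estimated under constant light.
#'
#' @param params Full 56-parameter vector.
#' @param schedules Character vector (or list of schedule objects).
#' @param ... Passed to [entrain_then_switch()].
#' @return Named list of `clock_trajectory` objects.
#' @export
predict_under_photoperiods <- function(params = default_params(),
                                       schedules = c("12L12D", "24L",
                                                     "6L6D", "3L3D"), ...) {
  if (length(schedules) == 0) stop("schedule list is empty", call. = FALSE)
  out <- lapply(schedules, function(s)
    entrain_then_switch(params, target = s, ...))
  names(out) <- vapply(out, function(tr) tr$schedule_name, character(1))
  out
}
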