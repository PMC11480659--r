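# Shared fixtures built in code. Expensive entrained trajectories are
# memoised so several test files can reuse them within one run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

entrained_12l12d <- function() cached("tr12",
  entrain_then_switch(default_params(), target = "12L12D", post_days = 5))

entrained_24l <- function() cached("tr24",
  entrain_then_switch(default_params(), target = "24L", post_days = 6))

sinusoid_series <- function(period_h = 24, phase_h = 6, amplitude = 1,
                            baseline = 0, t_max = 120, dt = 0.05) {
  tt <- seq(0, t_max, by = dt)
  data.frame(time_h = tt,
             value = baseline +
               amplitude * cos(2 * pi * (tt - phase_h) / period_h))
}

peak_zt <- function(traj, var, day = 4) {
  s <- trajectory_series(traj, var)
  sel <- s$time_h >= 24 * day & s$time_h < 24 * (day + 1)
  s$time_h[sel][which.max(s$value[sel])] %% 24
}
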