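#!/usr/bin/env Rscript

# Calibration diagnostics for a candidate basal parameter set: prints the
# entrained phase anchors, the entrained and free-running periods, and the
# first-cycle constant-light peak delay. This is the report used when the
# packaged basal set was frozen; edit `params` below (or source your own)
# to re-evaluate a candidate.

suppressPackageStartupMessages(library(circaphoto))

params <- default_params()

tr12 <- entrain_then_switch(params, target = "12L12D", post_days = 5)
tr24 <- entrain_then_switch(params, target = "24L", post_days = 6)

peak_zt <- function(traj, var, day = 4) {
  s <- trajectory_series(traj, var)
  sel <- s$time_h >= 24 * day & s$time_h < 24 * (day + 1)
  s$time_h[sel][which.max(s$value[sel])] %% 24
}

cat("Entrained (12L12D) transcript peak phases [target]:\n")
anchors <- c(MCL = "ZT0", MP97 = "ZT6-9", MP51 = "ZT12", MEL = "ZT12-15",
             M_Lhcb1 = "light phase", M_RbcS1 = "dark phase",
             M_atpA = "dark phase")
for (v in names(anchors))
  cat(sprintf("  %-8s ZT %5.2f  [%s]\n", v, peak_zt(tr12, v), anchors[v]))

per12 <- estimate_period(trajectory_series(tr12, "M_Lhcb1"))$period_h
s24 <- trajectory_series(tr24, "M_Lhcb1")
per24 <- estimate_period(s24[s24$time_h >= 24, ])$period_h
cat(sprintf("\nLhcb1 period: 12L12D %.3f h [24.11], 24L %.3f h [25.85]\n",
            per12, per24))

delays <- vapply(c("M_Lhcb1", "M_RbcS1", "M_atpA"), function(v)
  first_peak_time(trajectory_series(tr24, v)) -
    first_peak_time(trajectory_series(tr12, v)), numeric(1))
cat(sprintf("First-cycle 24L peak delay: %s h, mean %.2f [>= 1]\n",
            paste(sprintf("%.2f", delays), collapse = ", "), mean(delays)))

stopifnot(min(tr12$states) > -1e-9)
cat("Non-negativity along the entrained trajectory: ok\n")
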