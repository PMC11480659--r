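test_that("period, phase and amplitude are recovered from clean sinusoids", {
  s24 <- sinusoid_series(period_h = 24, phase_h = 6)
  rs <- estimate_period(s24)
  expect_equal(rs$period_h, 24, tolerance = 0.05 / 24)
  expect_equal(rs$phase_h, 6, tolerance = 0.1 / 6)
  expect_equal(rs$amplitude, 1, tolerance = 1e-3)
  expect_equal(rs$n_peaks_used, 5)

  # skeleton-induced period halving is detectable
  s12 <- sinusoid_series(period_h = 12, phase_h = 3)
  expect_equal(estimate_period(s12)$period_h, 12, tolerance = 0.05 / 12)
})

test_that("period estimation is robust to 5% additive noise", {
  set.seed(71)
  worst <- 0
  for (i in 1:100) {
    T0 <- runif(1, 18, 30)
    s <- sinusoid_series(period_h = T0, phase_h = runif(1, 0, T0))
    s$value <- s$value + rnorm(nrow(s), 0, 0.05)
    rel <- abs(estimate_period(s, expected_period_h = T0)$period_h - T0) / T0
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.02)
})

test_that("non-rhythmic series raise a rhythm-undetectable condition", {
  flat <- data.frame(time_h = seq(0, 120, 0.5), value = seq(0, 1, length.out = 241))
  expect_error(estimate_period(flat), class = "rhythm_undetectable")
  short <- sinusoid_series(t_max = 40)
  expect_error(estimate_period(short), "cycles")
  coarse <- sinusoid_series(t_max = 96, dt = 6)
  expect_error(estimate_period(coarse), "8 points")
})

test_that("the error measure is the printed sum of squares", {
  g <- function(v) data.frame(time_h = seq_along(v), value = v)
  expect_equal(mse(g(c(1, 2)), g(c(1, 2))), 0)
  expect_equal(mse(g(c(1, 2)), g(c(1, 1))), 1)
  expect_equal(mse(g(c(0, 3, 0)), g(c(1, 1, 1))), 6)
  expect_equal(mse(g(c(0, 3, 0)), g(c(1, 1, 1)), normalized = TRUE), 2)
  expect_error(mse(g(1:3), g(1:4)), "grid")
  expect_error(mse(data.frame(time_h = c(1, 2), value = c(1, 1)),
                   data.frame(time_h = c(1, 3), value = c(1, 1))), "grid")
})

test_that("the simple cost sums squared errors over the photosynthetic genes", {
  g <- function(v) data.frame(time_h = seq_along(v), value = v)
  sim <- list(Lhcb1 = g(c(1, 2)), RbcS1 = g(c(0, 0)), atpA = g(c(1, 1)))
  obs <- list(Lhcb1 = g(c(1, 2)), RbcS1 = g(c(1, 1)), atpA = g(c(2, 2)))
  expect_equal(cost_simple(sim, sim), 0)
  expect_equal(cost_simple(sim, obs), 0 + 2 + 2)
  # dropping a gene with positive error strictly decreases the cost
  expect_lt(cost_simple(sim, obs, genes = c("Lhcb1", "atpA")),
            cost_simple(sim, obs))
  expect_error(cost_simple(sim, obs, genes = "GI"), "missing")
  expect_error(cost_simple(sim, obs, genes = character(0)), "empty")
})

test_that("the extended cost decomposes into SSE, phase and period terms", {
  s <- sinusoid_series(period_h = 24, phase_h = 6)
  same <- cost_optimal(list(g = s), list(g = s), genes = "g")
  expect_equal(same$sse, 0)
  expect_equal(same$phase_err, 0)
  expect_equal(same$period_err, 0)
  expect_equal(same$total, 0)

  # +2 h shift, same period: phase term 4, period term ~0
  shifted <- sinusoid_series(period_h = 24, phase_h = 8)
  cb <- cost_optimal(list(g = shifted), list(g = s), genes = "g")
  expect_equal(cb$phase_err, 4, tolerance = 0.02)
  expect_lt(cb$period_err, 1e-3)
  expect_equal(cb$total, cb$sse + cb$phase_err + cb$period_err)

  # period 26 vs 24: period term 4
  slow <- sinusoid_series(period_h = 26, phase_h = 6)
  cb2 <- cost_optimal(list(g = slow), list(g = s), genes = "g")
  expect_equal(cb2$period_err, 4, tolerance = 0.05)

  # shifting by exactly one period is free in the phase term
  wrapped <- sinusoid_series(period_h = 24, phase_h = 6 + 24)
  cb3 <- cost_optimal(list(g = wrapped), list(g = s), genes = "g")
  expect_lt(cb3$phase_err, 1e-3)

  # scale covariance: values scaled by c scale SSE by c^2, leave
  # phase/period terms unchanged
  sc <- function(x, c) { x$value <- x$value * c; x }
  cb4 <- cost_optimal(list(g = sc(shifted, 3)), list(g = sc(s, 3)),
                      genes = "g")
  expect_equal(cb4$sse, 9 * cb$sse, tolerance = 1e-8)
  expect_equal(cb4$phase_err, cb$phase_err, tolerance = 1e-8)

  # arrhythmic series contribute only SSE, with a warning
  flat <- data.frame(time_h = s$time_h, value = rep(1, nrow(s)))
  expect_warning(cb5 <- cost_optimal(list(g = flat), list(g = s), genes = "g"),
                 "not rhythmic")
  expect_equal(cb5$phase_err, 0)
  expect_gt(cb5$sse, 0)
})

test_that("first peak times are located inside a window", {
  s <- sinusoid_series(period_h = 24, phase_h = 5, t_max = 48)
  expect_equal(first_peak_time(s), 5, tolerance = 0.01)
  expect_error(first_peak_time(data.frame(time_h = 1:30, value = 1:30)),
               "no prominent peak")
})
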