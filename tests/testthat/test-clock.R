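test_that("Hill factors obey their algebraic identities and limits", {
  expect_equal(hill_repress(0, 1), 1)
  expect_equal(hill_activate(0, 1), 0)
  expect_equal(hill_repress(2, 2), 0.5)
  expect_equal(hill_activate(2, 2), 0.5)
  expect_lt(hill_repress(1e6, 1), 1e-10)
  expect_gt(hill_activate(1e6, 1), 1 - 1e-10)

  set.seed(21)
  x <- rexp(500); K <- rexp(500) + 0.01
  expect_equal(hill_activate(x, K) + hill_repress(x, K), rep(1, 500))
  # monotonicity
  xs <- sort(runif(100, 0, 10))
  expect_true(all(diff(hill_activate(xs, 1.3)) >= 0))
  expect_true(all(diff(hill_repress(xs, 1.3)) <= 0))

  expect_error(hill_repress(1, 0), "positive")
  expect_error(hill_activate(-1, 1), "non-negative")
})

test_that("the LWD1 Fourier series evaluates the printed coefficients", {
  f <- lwd_forcing_24l()
  expect_equal(f$fundamental_period_h, 26)
  expect_equal(lwd_value(f, 0), 0.4 + 0.1 + 1.52)
  expect_equal(lwd_value(f, 6.5), 0.45 - 0.1 + 1.52)
  # mean over one period equals the offset, for arbitrary coefficients
  g <- lwd_forcing(a1 = -1.3, b1 = 0.7, a2 = 2.1, b2 = -0.4, c0 = 5,
                   fundamental_period_h = 17)
  tt <- seq(0, 17, length.out = 100001)[-100001]
  expect_equal(mean(lwd_value(g, tt)), 5, tolerance = 1e-6)
  expect_error(lwd_forcing(1, 1, 1, 1, 1, fundamental_period_h = 0),
               "positive")
})

test_that("the model exposes 15 state variables and 56 named parameters", {
  expect_length(model_state_names(), 15)
  expect_length(clock_state_names(), 9)
  expect_length(photogene_state_names(), 6)
  p <- default_params()
  expect_length(p, 56)
  expect_length(default_clock_params(), 24)
  expect_length(default_photogene_params(), 12)
  expect_length(default_output_params(), 20)
  expect_silent(validate_params(p))
  bad <- p; bad[["k_tl"]] <- -1
  expect_error(validate_params(bad), "> 0")
  expect_error(validate_params(p[-1]), "56")
  expect_error(validate_params(unname(p)), "named")
})

test_that("clock derivatives behave at limiting states", {
  sched <- build_schedule("12L12D")
  zero <- setNames(rep(0, 9), clock_state_names())
  d <- clock_derivatives(zero, t = 18, schedule = sched)  # darkness
  # mass-action terms vanish at zero: protein derivatives are exactly 0
  expect_equal(unname(d[c("CL", "P97", "P51", "EL")]), rep(0, 4))
  # transcription at zero state is the basal production, non-negative
  expect_true(all(d[c("MCL", "MP97", "MP51", "MEL")] >= 0))
  # P relaxes to 1 in darkness
  expect_gt(d[["P"]], 0)
  near1 <- zero; near1[["P"]] <- 0.999
  expect_gt(clock_derivatives(near1, 18, schedule = sched)[["P"]], 0)
  expect_lt(clock_derivatives(near1, 18, schedule = sched)[["P"]],
            clock_derivatives(zero, 18, schedule = sched)[["P"]])

  expect_error(clock_derivatives(zero - 1, 0, schedule = sched),
               "non-negative")
})

test_that("transcription production is bounded by its maximal rates", {
  p <- default_clock_params()
  sched <- build_schedule("12L12D")
  lwd <- lwd_forcing_24l(24)
  set.seed(31)
  for (i in 1:50) {
    s <- setNames(c(rexp(8, 1 / 2), runif(1)), clock_state_names())
    d <- clock_derivatives(s, t = runif(1, 0, 48), params = p,
                           schedule = sched, lwd = lwd)
    bound_mcl <- p[["v_mcl"]] + p[["q_light"]] + p[["a_lwd_mcl"]]
    expect_lte(d[["MCL"]], bound_mcl)  # degradation only reduces it
    expect_lte(d[["MP97"]], p[["v_mp97"]] + p[["q_light"]] + p[["a_lwd_prr"]])
    expect_lte(d[["MP51"]], p[["v_mp51"]] + p[["a_lwd_prr"]])
    expect_lte(d[["MEL"]], p[["v_mel"]])
  }
})

test_that("removing light and LWD input makes derivatives time-invariant", {
  p <- default_clock_params()
  p[c("a_lwd_mcl", "a_lwd_prr")] <- 0
  s24 <- build_schedule("24L")  # L = 1 at every t, no dark transitions
  lwd <- lwd_forcing_24l(26)
  st <- setNames(c(rexp(8), 0), clock_state_names())
  set.seed(5)
  st[["P"]] <- 0
  d1 <- clock_derivatives(st, t = 3.2, params = p, schedule = s24, lwd = lwd)
  d2 <- clock_derivatives(st, t = 17.9, params = p, schedule = s24, lwd = lwd)
  expect_identical(d1, d2)
})

test_that("trajectories stay non-negative and P stays in [0, 1] under parameter perturbation", {
  set.seed(41)
  base <- default_params()
  for (i in 1:10) {
    p <- base * runif(length(base), 0.8, 1.2)
    names(p) <- names(base)
    m <- clock_model(p, schedule = sample(c("12L12D", "6L6D", "3L3D"), 1))
    tr <- simulate(m, days = 4, dt = 0.05)
    expect_gte(min(tr$states), -1e-9)
    expect_true(all(tr$states[, "P"] <= 1 + 1e-9))
  }
})

test_that("the entrained model matches the observed phase ordering under 12L12D", {
  tr <- entrained_12l12d()
  # transcript peak phases on the 5th entrained day
  expect_lt(min(peak_zt(tr, "MCL"), 24 - peak_zt(tr, "MCL")), 1.5)  # dawn
  p97 <- peak_zt(tr, "MP97")
  expect_gte(p97, 6 - 1.5); expect_lte(p97, 9 + 1.5)
  p51 <- peak_zt(tr, "MP51")
  expect_gte(p51, 12 - 1.5); expect_lte(p51, 12 + 1.5)  # dusk
  el <- peak_zt(tr, "MEL")
  expect_gte(el, 12 - 1.5); expect_lte(el, 15 + 1.5)
  # every state variable entrains to the 24 h forcing
  for (v in model_state_names()) {
    rs <- estimate_period(trajectory_series(tr, v))
    expect_equal(rs$period_h, 24, tolerance = 0.2 / 24)
  }
})
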