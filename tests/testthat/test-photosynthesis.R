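test_that("the saturating photosynthetic map hits its anchor points", {
  pars <- c(alpha = 1.2, K1 = 1, H1 = 1, H2 = 1, H3 = 1)
  expect_equal(photosynthetic_rate(0, c(0, 0, 0), pars), 1.2)
  # four half-saturated terms add exactly 2
  expect_equal(photosynthetic_rate(1, c(1, 1, 1), pars), 1.2 + 2)
  # saturation bound alpha + 4
  expect_lte(photosynthetic_rate(1e8, c(1e8, 1e8, 1e8), pars), 1.2 + 4)
  expect_lt(photosynthetic_rate(100, c(100, 100, 100), pars), 1.2 + 4)
  expect_equal(photosynthetic_rate(1e8, c(1e8, 1e8, 1e8), pars), 5.2,
               tolerance = 1e-10)
  # prefixed parameter slices work the same
  expect_equal(
    photosynthetic_rate(0.7, c(2, 1, 3), default_output_params()[1:5]),
    photosynthetic_rate(0.7, c(2, 1, 3),
                        setNames(default_output_params()[1:5],
                                 c("alpha", "K1", "H1", "H2", "H3"))))
  expect_error(photosynthetic_rate(1, c(1, 1, 1),
                                   c(alpha = 1, K1 = 0, H1 = 1, H2 = 1, H3 = 1)),
               "> 0")
})

test_that("P_i is bounded in [alpha, alpha+4] and monotone in every input", {
  set.seed(51)
  for (i in 1:100) {
    pars <- c(alpha = runif(1, 0, 3), K1 = rexp(1) + 0.05,
              H1 = rexp(1) + 0.05, H2 = rexp(1) + 0.05, H3 = rexp(1) + 0.05)
    CL <- rexp(1, 1 / 2); X <- rexp(3, 1 / 2)
    v <- photosynthetic_rate(CL, X, pars)
    expect_gte(v, pars[["alpha"]])
    expect_lte(v, pars[["alpha"]] + 4)
    # non-decreasing in CL and each transcript
    expect_gte(photosynthetic_rate(CL * 1.5, X, pars), v)
    for (j in 1:3) {
      X2 <- X; X2[j] <- X2[j] * 1.5
      expect_gte(photosynthetic_rate(CL, X2, pars), v)
    }
    # doubling a half-saturation weakens the corresponding term
    p2 <- pars; p2[["H2"]] <- pars[["H2"]] * 2
    expect_lt(photosynthetic_rate(CL, X, p2), v)
  }
})

test_that("photogene derivatives respect the CL wiring and fixed points", {
  sched <- build_schedule("12L12D")
  zero6 <- setNames(rep(0, 6), photogene_state_names())
  clock0 <- setNames(rep(0, 9), clock_state_names())
  p <- default_photogene_params()

  # CL = 0: Lhcb1 activation term vanishes, RbcS1/atpA fully derepressed
  d_dark <- photogene_derivatives(zero6, clock0, t = 18, params = p,
                                  schedule = sched)
  expect_equal(d_dark[["M_Lhcb1"]], 0)   # no CL, no light
  expect_equal(d_dark[["M_RbcS1"]], p[["v_rbcs1"]])
  expect_equal(d_dark[["M_atpA"]], p[["v_atpa"]])
  d_light <- photogene_derivatives(zero6, clock0, t = 6, params = p,
                                   schedule = sched)
  expect_equal(d_light[["M_Lhcb1"]], p[["q_lhcb1"]])

  # zero state and zero production rates give an exact fixed point
  p0 <- p; p0[c("v_lhcb1", "v_rbcs1", "v_atpa", "q_lhcb1")] <- 0
  expect_equal(unname(photogene_derivatives(zero6, clock0, 18, p0, sched)),
               rep(0, 6))
  expect_error(photogene_derivatives(zero6 - 1, clock0, 0, p, sched),
               "non-negative")
})

test_that("simulated photosynthetic genes peak in the observed phases", {
  tr <- entrained_12l12d()
  lb <- peak_zt(tr, "M_Lhcb1")
  expect_gte(lb, 0); expect_lt(lb, 12)           # day-peaking
  expect_true(peak_zt(tr, "M_RbcS1") >= 12)      # night-peaking
  expect_true(peak_zt(tr, "M_atpA") >= 12)
})

test_that("the trajectory-to-photoparameter map is pointwise and memoryless", {
  const <- data.frame(time_h = seq(0, 24, by = 3), CL = 0.8,
                      M_Lhcb1 = 1.5, M_RbcS1 = 1.0, M_atpA = 1.2)
  out <- simulate_photoparams(const)
  expect_named(out, c("Pn", "Gs", "Ci", "Tr"))
  for (s in out) {
    expect_equal(s$time_h, const$time_h)
    expect_equal(diff(range(s$value)), 0)
  }
  # permuting rows permutes outputs identically (no state carried over)
  set.seed(61)
  vary <- data.frame(time_h = seq(0, 24, by = 3),
                     CL = rexp(9), M_Lhcb1 = rexp(9),
                     M_RbcS1 = rexp(9), M_atpA = rexp(9))
  ref <- simulate_photoparams(vary)
  perm <- sample(nrow(vary))
  out_perm <- simulate_photoparams(vary[perm, ])
  expect_equal(out_perm$Pn$value, ref$Pn$value[perm])
  expect_equal(out_perm$Ci$value, ref$Ci$value[perm])
  expect_error(simulate_photoparams(const[, -2]), "CL")
})

test_that("photosynthetic parameter series are 24 h-periodic under 12L12D", {
  tr <- entrained_12l12d()
  pp <- simulate_photoparams(tr)
  for (s in pp) {
    # compare the last two entrained days point by point
    day4 <- s$value[s$time_h >= 96 & s$time_h < 120]
    day3 <- s$value[s$time_h >= 72 & s$time_h < 96]
    expect_lt(max(abs(day4 - day3)) / diff(range(s$value)), 1e-3)
  }
})
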