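cpar <- controller_params(tau_gac = 24.1, tau_gde = 20.6, tau_tde = 8.7,
                          tau_tac = 9, t1 = 120, t2 = 176, t3 = 176)
tt <- seq(0, 400, by = 0.01)

test_that("a constant innervation is a fixed point of both filters", {
  N <- rep(0.3, length(tt))
  expect_equal(agonist_filter(tt, N, cpar), N, tolerance = 1e-12)
  expect_equal(antagonist_filter(tt, N, cpar), N, tolerance = 1e-12)
})

test_that("the step response matches the closed form to 1e-6 relative", {
  # constant tau regime: switch to amplitude A at t1, no further switch
  p <- controller_params(tau_gac = 24.1, tau_gde = 24.1, tau_tde = 8.7,
                         tau_tac = 9, t1 = 120, t2 = 1e6, t3 = 1e6)
  A <- 1.3
  N <- ifelse(tt < 120, 0, A)
  Fa <- agonist_filter(tt, N, p, F0 = 0)
  after <- tt >= 120
  ref <- A * (1 - exp(-(tt[after] - 120) / 24.1))
  expect_lt(max(abs(Fa[after] - ref)) / A, 1e-6)
})

test_that("piecewise time constants stitch continuously at the switches", {
  A <- 1.1; S <- 0.45
  N <- ifelse(tt < 120, 0.2, ifelse(tt < 176, A, S))
  Fa <- agonist_filter(tt, N, cpar, F0 = 0.2)
  # segment-wise closed forms
  seg1 <- tt >= 120 & tt <= 176
  ref1 <- A + (0.2 - A) * exp(-(tt[seg1] - 120) / 24.1)
  expect_lt(max(abs(Fa[seg1] - ref1)), 1e-6)
  F_t2 <- A + (0.2 - A) * exp(-(176 - 120) / 24.1)
  seg2 <- tt >= 176
  ref2 <- S + (F_t2 - S) * exp(-(tt[seg2] - 176) / 20.6)
  expect_lt(max(abs(Fa[seg2] - ref2)), 2e-6)
  # continuity across the switch
  i2 <- which.min(abs(tt - 176))
  expect_lt(abs(Fa[i2] - Fa[i2 - 1]), 0.01)
})

test_that("the antagonist pause-step follows its piecewise closed form", {
  N <- ifelse(tt < 120, 0.3, ifelse(tt < 176, 0, 0.28))
  Ft <- antagonist_filter(tt, N, cpar, F0 = 0.3)
  seg1 <- tt >= 120 & tt <= 176
  expect_lt(max(abs(Ft[seg1] - 0.3 * exp(-(tt[seg1] - 120) / 8.7))),
            1e-6)
  F_t3 <- 0.3 * exp(-(176 - 120) / 8.7)
  seg2 <- tt >= 176
  ref2 <- 0.28 + (F_t3 - 0.28) * exp(-(tt[seg2] - 176) / 9)
  expect_lt(max(abs(Ft[seg2] - ref2)), 2e-6)
  # recovery begins exactly at t3
  i3 <- which.min(abs(tt - 176))
  expect_true(all(diff(Ft[seg2][1:100]) > 0))
  expect_lt(Ft[i3 - 1], 0.01)
})

test_that("fixation tensions recover the target through the equilibrium", {
  pp <- plant_from_config(default_config())
  ss0 <- steady_state_tensions(0, pp, F_0 = 0.297, alpha = 0.99)
  expect_equal(ss0$F_ag, ss0$F_ant)
  for (th in c(-5, 4, 12, 20)) {
    ss <- steady_state_tensions(th, pp, F_0 = 0.297, alpha = 0.99)
    eq <- plant_equilibrium(pp, ss$F_ag, ss$F_ant)
    expect_lt(abs(eq$theta_deg - th), 0.05)
    expect_gte(ss$F_ag, 0); expect_gte(ss$F_ant, 0)
  }
  f <- vapply(c(2, 8, 14, 20), function(th)
    unlist(steady_state_tensions(th, pp, 0.297, 0.99)[c("F_ag",
                                                        "F_ant")]),
    numeric(2))
  expect_true(all(diff(f[1, ]) > 0))    # agonist increases with target
  expect_true(all(diff(f[2, ]) <= 0))   # antagonist does not increase
})

test_that("the inactive-fiber program decays and re-rises as prescribed", {
  F0 <- 0.297; Fn <- 0.62
  Fi <- inactive_fiber_program(tt, cpar, F0, Fn)
  i1 <- which.min(abs(tt - 120))
  expect_equal(Fi[i1], F0, tolerance = 1e-9)        # continuity at t1
  seg <- tt >= 120 & tt <= 176
  expect_lt(max(abs(Fi[seg] - F0 * exp(-(tt[seg] - 120) / 24.1))),
            1e-6)                                    # decay closed form
  expect_equal(tail(Fi, 1), Fn, tolerance = 1e-3)    # settles at new fix
})

test_that("the filter output is bounded by the innervation envelope", {
  set.seed(7)
  N <- pmax(0, 0.4 + cumsum(rnorm(length(tt), 0, 0.002)))
  Fa <- agonist_filter(tt, N, cpar, F0 = N[1])
  run_lo <- cummin(N); run_hi <- cummax(N)
  expect_true(all(Fa >= run_lo - 1e-9 & Fa <= run_hi + 1e-9))
})
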