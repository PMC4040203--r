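whole <- list(K_se = 125, B_2 = 0.5, K_lt = 60.7, B_1 = 1.355,
              J_p = 5e-4, B_p = 0.054, K_p = 39.9, r = 0.01)
pp <- fiber_parameter_scaling(whole, n = 1, m = 100)

test_that("an unloaded resting column carries no tension", {
  m <- pp$m
  expect_equal(column_tension(rep(0, m + 2), 0, rep(0, m), pp,
                              "agonist"), 0)
  expect_equal(column_tension(rep(0, m + 2), 0, rep(0, m), pp,
                              "antagonist"), 0)
})

test_that("static column tension matches the hand-solved series circuit", {
  # agonist, uniform active tension F, all rates zero, end at x:
  # tendons y = -T/K_se, fibers y = (F - T)/K_lt, sum(y) = x
  # => T = (m F / K_lt - x) / (2/K_se + m/K_lt)
  m <- pp$m; F <- 0.5; x <- 1e-3
  Thand <- (m * F / pp$K_lt - x) / (2 / pp$K_se + m / pp$K_lt)
  y <- c(-Thand / pp$K_se, rep((F - Thand) / pp$K_lt, m),
         -Thand / pp$K_se)
  expect_equal(sum(y), x, tolerance = 1e-12)
  Tcode <- column_tension(y, 0, rep(F, m), pp, "agonist")
  expect_equal(Tcode, Thand, tolerance = 1e-10)
})

test_that("a single-fiber column reduces to the Voigt-plus-tendon form", {
  p1 <- fiber_parameter_scaling(whole, n = 1, m = 1)
  # static antagonist: tendon y = T/K_se (x2), fiber y = (T - F)/K_lt
  F <- 0.4; Tguess <- 0.25
  y <- c(Tguess / p1$K_se, (Tguess - F) / p1$K_lt, Tguess / p1$K_se)
  Tcode <- column_tension(y, 0, F, p1, "antagonist")
  expect_equal(Tcode, Tguess, tolerance = 1e-10)
})

test_that("net torques cancel for symmetric state and forcing", {
  m <- pp$m
  eq <- plant_equilibrium(pp, 0.3, 0.3)
  st <- list(x = eq$x, xd = 0, y_ag = eq$y_ag, y_ant = eq$y_ant)
  fo <- list(F_ag = rep(0.3, m), F_ant = rep(0.3, m))
  tq <- muscle_torques(st, fo, pp)
  expect_equal(tq$T_ag - tq$T_ant, 0, tolerance = 1e-10)
  # the printed sums agree with the column-tension computation path
  Ta <- column_tension(st$y_ag, 0, fo$F_ag, pp, "agonist")
  expect_equal(tq$T_ag, pp$n * Ta, tolerance = 1e-10)
})

test_that("the static equilibrium satisfies the closed-form angle", {
  ss <- steady_state_tensions(14, pp, 0.297, 0.99)
  eq <- plant_equilibrium(pp, ss$F_ag, ss$F_ant)
  st <- list(x = eq$x, xd = 0, y_ag = eq$y_ag, y_ant = eq$y_ant)
  fo <- list(F_ag = rep(ss$F_ag, pp$m), F_ant = rep(ss$F_ant, pp$m))
  d <- plant_derivatives(st, fo, pp)
  expect_lt(max(abs(c(d$dx, d$dxd, d$dy_ag, d$dy_ant))), 1e-9)
  # theta_ss = (T_ag - T_ant) / (K_p r) in radians
  th_rad <- (d$T_ag - d$T_ant) / (pp$K_p * pp$r)
  expect_equal(th_rad * 180 / pi, eq$theta_deg, tolerance = 1e-8)
})

test_that("an agonist tension step accelerates the eye forward", {
  eq <- plant_equilibrium(pp, 0.3, 0.3)
  st <- list(x = eq$x, xd = 0, y_ag = eq$y_ag, y_ant = eq$y_ant)
  fo <- list(F_ag = rep(0.45, pp$m), F_ant = rep(0.3, pp$m))
  d <- plant_derivatives(st, fo, pp)
  expect_gt(d$dxd, 0)
})

test_that("frozen fixation forcing holds the eye still", {
  tt <- seq(0, 100, by = 0.01)
  ss <- steady_state_tensions(6, pp, 0.297, 0.99)
  sim <- simulate_plant(tt, rep(ss$F_ag, length(tt)), NULL,
                        rep(ss$F_ant, length(tt)), pp)
  expect_lt(diff(range(sim$theta)), 1e-6)
  expect_equal(sim$theta[1], 6, tolerance = 0.05)
})

test_that("the passive plant returns toward the primary position", {
  tt <- seq(0, 600, by = 0.01)
  # start from a displaced equilibrium, then remove all active tension
  ss <- steady_state_tensions(8, pp, 0.297, 0.99)
  Fa <- ifelse(tt < 1, ss$F_ag, 0)
  Ft <- ifelse(tt < 1, ss$F_ant, 0)
  sim <- simulate_plant(tt, Fa, NULL, Ft, pp)
  expect_equal(sim$theta[1], 8, tolerance = 0.05)
  expect_lt(abs(tail(sim$theta, 1)), 0.4)
})

test_that("the fiber chain matches the whole-muscle reduction within 1%", {
  p100 <- fiber_parameter_scaling(whole, n = 1, m = 100)
  p1 <- fiber_parameter_scaling(whole, n = 1, m = 1)
  tt <- seq(0, 250, by = 0.01)
  cp <- controller_params(24.1, 20.6, 8.7, 9, t1 = 20, t2 = 76, t3 = 76)
  ss <- steady_state_tensions(16, p100, 0.297, 0.99)
  N <- ifelse(tt < 20, 0.297, ifelse(tt < 76, 0.45, ss$F_ag))
  Fa <- agonist_filter(tt, N, cp)
  Nant <- ifelse(tt < 20, 0.297, ifelse(tt < 76, 0, ss$F_ant))
  Ft <- antagonist_filter(tt, Nant, cp)
  s100 <- simulate_plant(tt, Fa, NULL, Ft, p100)
  s1 <- simulate_plant(tt, Fa, NULL, Ft, p1)
  rms <- sqrt(mean((s100$theta - s1$theta)^2))
  expect_lt(rms / max(abs(s100$theta)), 0.01)
})

test_that("series/parallel scaling preserves the aggregate stiffness", {
  agg <- function(p) {
    # static stiffness of one column: two tendons + m fibers in series
    1 / (2 / p$K_se + p$m / p$K_lt) * p$n
  }
  k_ref <- 1 / (1 / whole$K_se + 1 / whole$K_lt)
  expect_equal(agg(fiber_parameter_scaling(whole, 1, 1)), k_ref,
               tolerance = 1e-9)
  expect_equal(agg(fiber_parameter_scaling(whole, 1, 100)), k_ref,
               tolerance = 1e-9)
  expect_equal(agg(fiber_parameter_scaling(whole, 1, 200)), k_ref,
               tolerance = 1e-9)
})

test_that("the compiled plant step agrees with the R derivative field", {
  m <- pp$m
  tt <- seq(0, 0.5, by = 0.01)
  Fa <- matrix(0.45, length(tt), 1)
  Ft <- rep(0.2, length(tt))
  sim <- simulate_plant(tt, Fa, NULL, Ft, pp)
  # one small explicit Euler step from the same initial equilibrium
  eq <- plant_equilibrium(pp, 0.45, 0.2)
  st <- list(x = eq$x, xd = 0, y_ag = eq$y_ag, y_ant = eq$y_ant)
  d <- plant_derivatives(st, list(F_ag = rep(0.45, m),
                                  F_ant = rep(0.2, m)), pp)
  # equilibrium under the applied forcing: derivatives vanish and the
  # simulated trace stays put
  expect_lt(max(abs(c(d$dx, d$dxd))), 1e-9)
  expect_lt(diff(range(sim$theta)), 1e-8)
})
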