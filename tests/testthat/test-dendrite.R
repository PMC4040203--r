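# Independent DC oracle: solve the resistive ladder (tridiagonal
# conductance matrix) for the steady state under constant input current.
dendrite_dc_oracle <- function(params, I) {
  n <- params$n_compartments
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, i] <- 1 / params$R_EQ +
      (if (i > 1) 1 / params$R_a else 0) +
      (if (i < n) 1 / params$R_a else 0)
    if (i > 1) A[i, i - 1] <- -1 / params$R_a
    if (i < n) A[i, i + 1] <- -1 / params$R_a
  }
  b <- rep(params$V_TH / params$R_EQ, n)
  b[1] <- b[1] + I
  as.numeric(solve(A, b))
}

ebn_dendrite <- dendrite_params(14, C_m = 0.45, R_EQ = 3.1, R_a = 0.1,
                                V_TH = -60)

test_that("resting membrane stays at the Thevenin potential without input", {
  d <- dendrite_derivatives(rep(-60, 14), 0, ebn_dendrite)
  expect_equal(d, rep(0, 14))
  sim <- simulate_dendrite(stimulus_train(), ebn_dendrite,
                           duration = 200, dt = 0.01, record_dt = 1)
  expect_lt(max(abs(sim$v_m + 60)), 1e-9)
})

test_that("single-compartment steady state matches V_TH + I R_EQ", {
  p1 <- dendrite_params(1, C_m = 0.5, R_EQ = 2.5, V_TH = -60)
  I <- 4
  st <- stimulus_train(0, 400, I)
  sim <- simulate_dendrite(st, p1, duration = 100, dt = 0.01,
                           record_dt = 1)
  v_ss <- unname(sim$v_m[nrow(sim$v_m), 1])
  expect_equal(v_ss, -60 + I * 2.5, tolerance = 1e-6)
})

test_that("simulated DC steady state matches the ladder solve to <0.1%", {
  for (n in c(3L, 14L)) {
    p <- dendrite_params(n, C_m = 0.45, R_EQ = 3.1, R_a = 0.1,
                         V_TH = -60)
    I <- 10
    sim <- simulate_dendrite(stimulus_train(0, 1000, I), p,
                             duration = 400, dt = 0.01, record_dt = 5)
    v_sim <- sim$v_m[nrow(sim$v_m), ]
    v_ref <- dendrite_dc_oracle(p, I)
    expect_lt(max(abs(v_sim - v_ref) / abs(v_ref)), 1e-3)
  }
})

test_that("a pulse attenuates monotonically along the chain", {
  st <- stimulus_train(5, 1, 50)
  sim <- simulate_dendrite(st, ebn_dendrite, duration = 60, dt = 0.01)
  peak_dev <- apply(abs(sim$v_m + 60), 2, max)
  expect_true(all(diff(peak_dev) <= 1e-9))
  expect_gt(peak_dev[1], peak_dev[14] * 2)
})

test_that("the passive chain responds linearly to summed stimuli", {
  a <- stimulus_train(c(2, 9), c(1, 2), c(30, -12))
  b <- stimulus_train(c(5, 14), c(0.5, 3), c(18, 25))
  both <- stimulus_train(c(2, 5, 9, 14), c(1, 0.5, 2, 3),
                         c(30, 18, -12, 25))
  va <- simulate_dendrite(a, ebn_dendrite, 40, dt = 0.01)$v_m + 60
  vb <- simulate_dendrite(b, ebn_dendrite, 40, dt = 0.01)$v_m + 60
  vab <- simulate_dendrite(both, ebn_dendrite, 40, dt = 0.01)$v_m + 60
  expect_equal(vab, va + vb, tolerance = 1e-8)
})

test_that("a mismatched state vector is rejected", {
  expect_error(dendrite_derivatives(rep(-60, 5), 0, ebn_dendrite),
               "does not match")
})

test_that("the compiled integrator agrees with an R-level RK4 reference", {
  p <- dendrite_params(4, C_m = 0.45, R_EQ = 3.1, R_a = 0.1, V_TH = -60)
  st <- stimulus_train(1, 3, 40)
  dt <- 0.01
  tt <- seq(0, 10, by = dt)
  v <- rep(-60, 4)
  for (k in seq_len(length(tt) - 1)) {
    is <- eval_stimulus(st, tt[k])
    k1 <- dendrite_derivatives(v, is, p)
    k2 <- dendrite_derivatives(v + dt / 2 * k1, is, p)
    k3 <- dendrite_derivatives(v + dt / 2 * k2, is, p)
    k4 <- dendrite_derivatives(v + dt * k3, is, p)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  sim <- simulate_dendrite(st, p, duration = 10, dt = dt)
  expect_equal(as.numeric(sim$v_m[nrow(sim$v_m), ]), v,
               tolerance = 1e-10)
})
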