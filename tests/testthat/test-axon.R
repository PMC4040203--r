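basic <- hh_params("basic")
modif <- hh_params("modified")

test_that("gating rates reproduce the printed formulas and their limits", {
  r0 <- gating_rates(-60, basic)   # V = 0
  expect_equal(r0$beta_N, 0.125)
  expect_equal(r0$beta_M, 4)
  expect_equal(r0$alpha_H, 0.07)
  expect_equal(r0$alpha_N, 0.01 * 10 / (exp(1) - 1), tolerance = 1e-10)
  expect_equal(r0$beta_H, 1 / (exp(3) + 1), tolerance = 1e-10)
  # removable singularities evaluated by their limits
  r10 <- gating_rates(-50, basic)  # V = -10
  expect_equal(r10$alpha_N, 0.1, tolerance = 1e-6)
  rm10 <- gating_rates(-50, modif)
  expect_equal(rm10$alpha_M, 1.0, tolerance = 1e-6)
  # modified variant only changes alpha_M
  rb <- gating_rates(-55, basic); rm <- gating_rates(-55, modif)
  expect_false(isTRUE(all.equal(rb$alpha_M, rm$alpha_M)))
  for (nm in c("alpha_N", "beta_N", "beta_M", "alpha_H", "beta_H"))
    expect_equal(rb[[nm]], rm[[nm]])
})

test_that("the basic model is at equilibrium at rest", {
  s <- hh_resting_state(basic)
  d <- hh_derivatives(s, 0, basic)
  expect_lt(max(abs(d)), 0.01)
  # gating steady states are alpha / (alpha + beta)
  r <- gating_rates(-60, basic)
  expect_equal(unname(s["N"]), r$alpha_N / (r$alpha_N + r$beta_N))
})

test_that("the rate coefficient scales only the gating equations", {
  s <- c(V_m = -52, N = 0.4, M = 0.1, H = 0.5)
  d1 <- hh_derivatives(s, 5, hh_params("basic", rate_coefficient = 1))
  d9 <- hh_derivatives(s, 5, hh_params("basic", rate_coefficient = 9))
  expect_equal(unname(d9["V_m"]), unname(d1["V_m"]))
  expect_equal(unname(d9[c("N", "M", "H")]),
               unname(9 * d1[c("N", "M", "H")]))
})

test_that("the basic axon is silent at rest; the modified one fires alone", {
  sb <- simulate_axon(0, basic, duration = 150)
  expect_length(sb$spikes, 0)
  expect_equal(tail(sb$V_m, 1), -60, tolerance = 0.05)
  sm <- simulate_axon(0, modif, duration = 150)
  expect_gt(length(sm$spikes), 5)
})

test_that("a brief pulse just above threshold fires exactly one spike", {
  thr <- find_threshold_voltage(basic)
  trial <- function(amp) {
    Im <- c(rep(amp, 1000), rep(0, 39000))  # 1 ms pulse, 40 ms window
    length(simulate_axon(Im, basic, dt = 1e-3)$spikes)
  }
  expect_equal(trial(thr$amp_supra * 1.0005), 1)
  expect_equal(trial(thr$amp_sub * 0.995), 0)
})

test_that("gating variables stay in [0, 1] under random pulse trains", {
  set.seed(42)
  for (k in 1:4) {
    ons <- sort(runif(12, 0, 60))
    st <- stimulus_train(ons, runif(12, 0.3, 2), runif(12, -80, 120))
    tt <- seq(0, 70 - 1e-3, by = 1e-3)
    Im <- eval_stimulus(st, tt)
    p <- if (k %% 2) basic else hh_params("modified",
                                          rate_coefficient = 5)
    s <- simulate_axon(Im, p, dt = 1e-3)
    for (g in c("N", "M", "H")) {
      expect_gte(min(s[[g]]), 0)
      expect_lte(max(s[[g]]), 1)
    }
  }
})

test_that("rest is stable against subthreshold perturbations", {
  Im <- c(rep(3, 1000), rep(0, 59000))
  s <- simulate_axon(Im, basic, dt = 1e-3)
  expect_length(s$spikes, 0)
  expect_lt(abs(tail(s$V_m, 1) + 60), 0.5)
})

test_that("two suprathreshold pulses inside the refractory period fire once", {
  thr <- find_threshold_voltage(basic)
  amp <- thr$amp_supra * 3
  mk <- function(gap_ms) {
    tt <- seq(0, 40 - 1e-3, by = 1e-3)
    st <- stimulus_train(c(1, 1 + 1 + gap_ms), c(1, 1), amp)
    eval_stimulus(st, tt)
  }
  expect_equal(length(simulate_axon(mk(1), basic, dt = 1e-3)$spikes), 1)
  expect_equal(length(simulate_axon(mk(25), basic, dt = 1e-3)$spikes), 2)
})

test_that("peak firing rate grows with the gating-rate coefficient", {
  # over the coefficient range where repetitive spiking survives
  rates <- vapply(c(1, 2, 5, 10), function(cf) {
    p <- hh_params("modified", rate_coefficient = cf)
    s <- simulate_axon(50, p, duration = 80, dt = 1e-3)
    1000 / min(diff(s$spikes))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_gt(rates[4], 900)
})

test_that("firing thresholds sit near -45 mV (basic) and -60 mV (modified)", {
  tb <- find_threshold_voltage(basic)
  tm <- find_threshold_voltage(modif)
  expect_lt(abs(tb$threshold_mV - (-45)), 2)
  expect_lt(abs(tm$threshold_mV - (-60)), 2)
  expect_gt(tb$threshold_mV, tm$threshold_mV)
})

test_that("the exponential integrator matches an R-level RK4 reference", {
  p <- basic
  dt <- 1e-4
  tt <- seq(0, 12, by = dt)
  Im <- ifelse(tt >= 1 & tt < 2, 15, 0)
  s <- as.list(hh_resting_state(p)); names(s) <- c("V_m", "N", "M", "H")
  step <- function(s, I) {
    f <- function(x) hh_derivatives(x, I, p)
    x <- unlist(s)
    k1 <- f(x); k2 <- f(x + dt / 2 * k1); k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    as.list(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  }
  for (k in seq_len(length(tt) - 1)) s <- step(s, Im[k])
  sim <- simulate_axon(Im[-length(Im)], p, dt = dt, record_dt = dt)
  expect_equal(tail(sim$V_m, 1), s$V_m, tolerance = 0.02)
})
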