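#' Hodgkin-Huxley axon parameters
#'
#' Conductance-based spike generator at the axon hillock.  Two variants are
#' supported: `basic` is the classic squid-axon model (firing threshold
#' near -45 mV), and `modified` shifts the sodium activation rate
#' `alpha_M` so the cell's threshold drops to the resting potential,
#' letting it fire autonomously when released from inhibition (used by the
#' excitatory burst neuron and the omnipause neuron).
#'
#' Units: conductances in mS, potentials in mV, capacitance in uF,
#' resistance in kOhm, time in ms, so currents come out in uA.
#' `rate_coefficient` multiplies the right-hand side of all three gating
#' equations uniformly; it is the knob that sets the attainable peak
#' firing rate.
#'
#' @param variant `"basic"` or `"modified"`.
#' @param rate_coefficient positive multiplier on the gating kinetics.
#' @param g_K,g_Na maximal potassium / sodium conductances (mS).
#' @param E_K,E_Na,E_l battery potentials (mV; signed, circuit convention
#'   with rest at -60 mV).
#' @param R_l leakage resistance (kOhm).
#' @param C_m axon membrane capacitance (uF).
#' @param V_rp resting potential (mV).
#' @param gain_in dimensionless gain on the dendro-axonal coupling current.
#' @return An object of class `hh_params`.
#' @export
hh_params <- function(variant = c("basic", "modified"),
                      rate_coefficient = 1,
                      g_K = 36, g_Na = 120,
                      E_K = -72, E_Na = 55, E_l = -49.4,
                      R_l = 3.33, C_m = 1, V_rp = -60, gain_in = 1) {
  variant <- match.arg(variant)
  stopifnot(g_K > 0, g_Na > 0, R_l > 0, C_m > 0, rate_coefficient > 0)
  structure(list(variant = variant, rate_coefficient = rate_coefficient,
                 g_K = g_K, g_Na = g_Na, E_K = E_K, E_Na = E_Na, E_l = E_l,
                 R_l = R_l, C_m = C_m, V_rp = V_rp, gain_in = gain_in),
            class = "hh_params")
}

# x / (exp(x/den) - 1), with the removable singularity evaluated by limit.
vtrap <- function(x, den) {
  r <- x / den
  small <- abs(r) < 1e-7
  out <- numeric(length(x))
  out[small] <- den * (1 - r[small] / 2)
  out[!small] <- x[!small] / (exp(r[!small]) - 1)
  out
}

#' Gating rate functions
#'
#' Evaluates the six voltage-dependent rate coefficients (ms^-1) at a
#' membrane potential, in the classic displacement coordinate
#' `V = V_rp - V_m` (depolarisation negative).  The `modified` variant
#' replaces `alpha_M`'s (V+25) terms with (V+10).
#'
#' @param V_m membrane potential (mV).
#' @param params an [hh_params()].
#' @return Named list with `alpha_N`, `beta_N`, `alpha_M`, `beta_M`,
#'   `alpha_H`, `beta_H`.
#' @export
gating_rates <- function(V_m, params) {
  V <- params$V_rp - V_m
  list(
    alpha_N = 0.01 * vtrap(V + 10, 10),
    beta_N  = 0.125 * exp(V / 80),
    alpha_M = if (params$variant == "modified") 0.1 * vtrap(V + 10, 10)
              else 0.1 * vtrap(V + 25, 10),
    beta_M  = 4 * exp(V / 18),
    alpha_H = 0.07 * exp(V / 20),
    beta_H  = 1 / (exp((V + 30) / 10) + 1)
  )
}

#' Hodgkin-Huxley state derivatives
#'
#' Membrane equation plus the three gating equations, the latter
#' multiplied by `rate_coefficient`.
#'
#' @param state named list or vector with `V_m`, `N`, `M`, `H`.
#' @param I_m membrane (dendritic coupling) current, uA.
#' @param params an [hh_params()].
#' @return Named vector of derivatives (mV/ms and 1/ms).
#' @export
hh_derivatives <- function(state, I_m, params) {
  s <- as.list(state)
  stopifnot(s$N >= 0, s$N <= 1, s$M >= 0, s$M <= 1, s$H >= 0, s$H <= 1)
  r <- gating_rates(s$V_m, params)
  gK <- params$g_K * s$N^4
  gNa <- params$g_Na * s$M^3 * s$H
  ionic <- gK * (s$V_m - params$E_K) + gNa * (s$V_m - params$E_Na) +
    (s$V_m - params$E_l) / params$R_l
  cf <- params$rate_coefficient
  c(V_m = (I_m - ionic) / params$C_m,
    N = cf * (r$alpha_N * (1 - s$N) - r$beta_N * s$N),
    M = cf * (r$alpha_M * (1 - s$M) - r$beta_M * s$M),
    H = cf * (r$alpha_H * (1 - s$H) - r$beta_H * s$H))
}

#' Resting gating state
#'
#' Steady-state gating values alpha/(alpha+beta) at the resting potential.
#'
#' @param params an [hh_params()].
#' @return Named vector `V_m`, `N`, `M`, `H`.
#' @export
hh_resting_state <- function(params) {
  r <- gating_rates(params$V_rp, params)
  c(V_m = params$V_rp,
    N = r$alpha_N / (r$alpha_N + r$beta_N),
    M = r$alpha_M / (r$alpha_M + r$beta_M),
    H = r$alpha_H / (r$alpha_H + r$beta_H))
}

#' Simulate the axon under a membrane current
#'
#' Integrates the spike generator from its resting equilibrium using a
#' Rush-Larsen (exponential) update for the gating variables and an
#' exponential-Euler update for the membrane potential; both remain stable
#' for arbitrarily large `rate_coefficient`.
#'
#' @param I_m membrane current: a single number (constant), a function of
#'   time (ms), or a vector sampled at `dt`.
#' @param params an [hh_params()].
#' @param duration simulation length (ms); ignored when `I_m` is a vector.
#' @param dt integration step (ms).
#' @param record_dt sampling step of the returned trace (ms).
#' @param spike_level membrane potential whose upward crossings are
#'   reported as spike times (mV).
#' @return List with `time`, `V_m`, gating traces and `spikes` (ms).
#' @export
simulate_axon <- function(I_m, params, duration = NULL, dt = 1e-3,
                          record_dt = 0.01, spike_level = 0) {
  if (is.function(I_m)) {
    stopifnot(!is.null(duration))
    I_m <- I_m(seq(0, duration - dt, by = dt))
  } else if (length(I_m) == 1) {
    stopifnot(!is.null(duration))
    I_m <- rep(I_m, round(duration / dt))
  }
  record_every <- max(1L, as.integer(round(record_dt / dt)))
  cpp_simulate_axon(as.numeric(I_m), params, dt, record_every, spike_level)
}

#' Firing threshold voltage by pulse bisection
#'
#' Applies brief (default 1 ms) current pulses of varying amplitude to the
#' axon at rest and bisects to the marginal (rheobase) amplitude -- the
#' boundary between the largest amplitude that fails to elicit a spike
#' inside the observation window and the smallest that succeeds.  The
#' reported threshold is the membrane potential at spike initiation on the
#' marginal trial, read off where dV/dt first exceeds the take-off
#' criterion (default 10 mV/ms, the standard operational definition):
#' near rheobase the trajectory lingers at the unstable take-off potential
#' before the regenerative upstroke, so the estimate converges as the
#' bracket tightens.  The autonomously firing `modified` variant spikes
#' with no stimulus at all (its rheobase is zero); its take-off is then
#' measured directly on the stimulus-free trial and evaluates to the
#' resting potential.
#'
#' @param params an [hh_params()].
#' @param pulse_ms stimulus pulse width (ms).
#' @param window_ms observation window per trial (ms).
#' @param tol_mV convergence tolerance on the returned potential (mV).
#' @param dvdt_crit take-off criterion on dV/dt (mV/ms).
#' @param max_iter maximum bisection steps.
#' @param dt integration step (ms).
#' @return List with `threshold_mV`, the bracketing amplitudes
#'   (`amp_sub`, `amp_supra`, uA) and the number of iterations.
#' @export
find_threshold_voltage <- function(params, pulse_ms = 1, window_ms = 25,
                                   tol_mV = 0.5, dvdt_crit = 10,
                                   max_iter = 60, dt = 1e-3) {
  nstep <- round(window_ms / dt)
  npulse <- round(pulse_ms / dt)
  trial <- function(amp) {
    Im <- c(rep(amp, npulse), rep(0, nstep - npulse))
    out <- cpp_simulate_axon(Im, params, dt, 1L, 0)
    spiked <- length(out$spikes) > 0
    v_takeoff <- NA_real_
    if (spiked) {
      v <- out$V_m
      ipk <- which(v >= 0)[1]
      dv <- diff(v[seq_len(ipk)]) / dt
      i0 <- which(dv > dvdt_crit)[1]
      v_takeoff <- v[i0]
    }
    list(spiked = spiked, v_takeoff = v_takeoff)
  }
  t0 <- trial(0)
  if (t0$spiked)
    return(list(threshold_mV = t0$v_takeoff, amp_sub = NA_real_,
                amp_supra = 0, iterations = 0L))
  lo <- 0
  hi <- 10
  while (!trial(hi)$spiked) {
    hi <- hi * 2
    if (hi > 1e5) stop("threshold bisection failed to bracket")
  }
  v_est <- trial(hi)$v_takeoff
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > max_iter)
      stop("threshold bisection did not converge after ", max_iter, " steps")
    mid <- (lo + hi) / 2
    tm <- trial(mid)
    if (tm$spiked) {
      hi <- mid
      if (abs(tm$v_takeoff - v_est) < tol_mV && iter >= 10) {
        v_est <- tm$v_takeoff
        break
      }
      v_est <- tm$v_takeoff
    } else {
      lo <- mid
    }
    if (hi - lo < 1e-12 * max(1, hi)) break
  }
  list(threshold_mV = v_est, amp_sub = lo, amp_supra = hi,
       iterations = iter)
}
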