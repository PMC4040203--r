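#' FitzHugh-Nagumo tonic unit parameters
#'
#' The tonic neuron (TN) and interneuron (IN) are two-variable relaxation
#' oscillators operating in a tonic-spiking regime:
#' \deqn{dv/dt = k (v - v^3/3 - w + I), \quad dw/dt = k \epsilon (v + a - b w)}
#' with input current `I` assembled from a constant baseline, the smoothed
#' dendritic potential, and (for the TN) an accumulated burst integral.
#' Above the oscillation onset the spike rate grows with `I`, which is how
#' a tonic rate encodes held eye position.
#'
#' @param a,b,eps dimensionless oscillator constants.
#' @param timescale rate multiplier `k` (1/ms); sets the spike width and
#'   the attainable tonic rates.
#' @param I_base baseline drive during fixation (dimensionless).
#' @param gain_dendrite input gain per mV of dendritic deviation.
#' @param gain_integrator input gain per uA ms of accumulated drive.
#' @param w_inhibitory weight of inhibitory synaptic current in the
#'   accumulator (1 = integrate it, 0 = shunting only).
#' @param tau_leak accumulator leak time constant (ms); 0 gives the
#'   perfect (leak-free) integrator used by the tonic neuron, a positive
#'   value a leaky integrator whose steady state tracks the mean input
#'   current (the interneuron's rate-tracking mechanism).
#' @return An object of class `fhn_params`.
#' @export
fhn_params <- function(a = 0.7, b = 0.8, eps = 0.08, timescale = 0.4,
                       I_base = 0.5, gain_dendrite = 0.02,
                       gain_integrator = 0, w_inhibitory = 1,
                       tau_leak = 0) {
  stopifnot(eps > 0, timescale > 0, tau_leak >= 0)
  structure(list(a = a, b = b, eps = eps, timescale = timescale,
                 I_base = I_base, gain_dendrite = gain_dendrite,
                 gain_integrator = gain_integrator,
                 w_inhibitory = w_inhibitory, tau_leak = tau_leak),
            class = "fhn_params")
}

#' FitzHugh-Nagumo derivatives
#'
#' @param state named list or vector with `v` (fast) and `w` (recovery).
#' @param input_current additive drive `I` (dimensionless).
#' @param params an [fhn_params()].
#' @return Named vector `v`, `w` of time derivatives (1/ms).
#' @export
fhn_derivatives <- function(state, input_current, params) {
  s <- as.list(state)
  k <- params$timescale
  c(v = k * (s$v - s$v^3 / 3 - s$w + input_current),
    w = k * params$eps * (s$v + params$a - params$b * s$w))
}

#' Simulate a tonic unit
#'
#' @param I drive: a constant, a function of time (ms), or a vector
#'   sampled at `dt`.
#' @param params an [fhn_params()].
#' @param duration simulation length (ms); ignored for vector input.
#' @param dt integration step (ms).
#' @param record_dt trace sampling step (ms).
#' @param spike_level upward crossings of the fast variable reported as
#'   spikes.
#' @return List with `time`, `v`, `w`, `spikes`.
#' @export
simulate_fhn <- function(I, params, duration = NULL, dt = 1e-3,
                         record_dt = 0.01, spike_level = 1) {
  if (is.function(I)) {
    stopifnot(!is.null(duration))
    I <- I(seq(0, duration - dt, by = dt))
  } else if (length(I) == 1) {
    stopifnot(!is.null(duration))
    I <- rep(I, round(duration / dt))
  }
  record_every <- max(1L, as.integer(round(record_dt / dt)))
  cpp_simulate_fhn(as.numeric(I), params, dt, record_every, spike_level,
                   -1.2, -0.62)
}

#' Accumulate burst drive
#'
#' Trapezoidal accumulation of a (net) synaptic input current; the
#' accumulated drive is what sets the tonic firing level once the burst
#' has ended.  The integrator is leak-free: fixation tension is constant
#' by construction.
#'
#' @param time sample times (ms).
#' @param input_current net input current samples (uA; excitatory
#'   positive).
#' @param acc0 initial accumulated drive (uA ms).
#' @return Final accumulated drive (uA ms).
#' @export
integrate_burst <- function(time, input_current, acc0 = 0) {
  if (length(time) < 2) return(acc0)
  dt <- diff(time)
  acc0 + sum(dt * (input_current[-length(input_current)] +
                     input_current[-1]) / 2)
}

#' Tonic firing rate for a held eye position
#'
#' Affine rate-position map used during fixation: `rate = rate_0 +
#' slope * theta`.  The inverse map is defined on any range where the
#' slope is nonzero.
#'
#' @param theta eye position (degrees).
#' @param calibration list with `rate_0` (Hz at primary position) and
#'   `slope` (Hz/degree).
#' @return Firing rate (Hz).
#' @export
tonic_rate_from_position <- function(theta, calibration) {
  calibration$rate_0 + calibration$slope * theta
}

#' @rdname tonic_rate_from_position
#' @param rate firing rate (Hz).
#' @export
position_from_tonic_rate <- function(rate, calibration) {
  (rate - calibration$rate_0) / calibration$slope
}
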