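#' Passive dendrite parameters
#'
#' A dendrite is modelled as a chain of `n_compartments` identical passive
#' RC compartments (membrane capacitance `C_m`, membrane resistance `R_EQ`,
#' resting electromotive force `V_TH`) coupled by the axial resistance
#' `R_a`.  Synaptic current enters the first compartment only; the axon
#' hillock taps the last compartment.  Units are chosen so that
#' uA x kOhm = mV with time in ms.
#'
#' @param n_compartments number of compartments (>= 1).
#' @param C_m membrane capacitance per compartment (uF).
#' @param R_EQ membrane resistance per compartment (kOhm).
#' @param R_a axial resistance between compartments (kOhm; 0.1 kOhm =
#'   100 Ohm, shared across neuron types).
#' @param V_TH Thevenin equivalent resting potential (mV).
#' @return An object of class `dendrite_params`.
#' @export
dendrite_params <- function(n_compartments = 14L, C_m = 0.45, R_EQ = 3.1,
                            R_a = 0.1, V_TH = -60) {
  n_compartments <- as.integer(n_compartments)
  stopifnot(n_compartments >= 1L, C_m > 0, R_EQ > 0, R_a > 0)
  structure(list(n_compartments = n_compartments, C_m = C_m, R_EQ = R_EQ,
                 R_a = R_a, V_TH = V_TH),
            class = "dendrite_params")
}

#' Rectangular current pulse train
#'
#' A presynaptic stimulus is a train of rectangular current pulses, each
#' described by an onset time, a width and a signed amplitude (positive
#' excitatory, negative inhibitory).
#'
#' @param onset pulse onset times (ms, nondecreasing).
#' @param width pulse widths (ms, > 0).
#' @param amplitude signed amplitudes (uA); recycled to the number of
#'   pulses.
#' @return A `stimulus_train` data frame with columns onset, width,
#'   amplitude.
#' @export
stimulus_train <- function(onset = numeric(), width = numeric(),
                           amplitude = numeric()) {
  k <- length(onset)
  if (k > 0) {
    width <- rep_len(width, k)
    amplitude <- rep_len(amplitude, k)
    stopifnot(all(width > 0), !is.unsorted(onset))
  } else {
    width <- numeric()
    amplitude <- numeric()
  }
  structure(data.frame(onset = as.numeric(onset), width = as.numeric(width),
                       amplitude = as.numeric(amplitude)),
            class = c("stimulus_train", "data.frame"))
}

#' Evaluate a pulse train at given times
#'
#' @param stim a [stimulus_train()].
#' @param t times (ms).
#' @return Summed pulse current i_s(t) in uA (pulses are active on
#'   `[onset, onset + width)`).
#' @export
eval_stimulus <- function(stim, t) {
  out <- numeric(length(t))
  for (r in seq_len(nrow(stim))) {
    on <- t >= stim$onset[r] & t < stim$onset[r] + stim$width[r]
    out[on] <- out[on] + stim$amplitude[r]
  }
  out
}

#' Periodic pulse train at a given firing rate
#'
#' Convenience constructor for scripted drives: pulses at instantaneous
#' rate `rate` (Hz), optionally ramping linearly to `rate_end` over the
#' train (the envelope used for the collicular drive).
#'
#' @param t_on train onset (ms).
#' @param duration train duration (ms).
#' @param rate initial pulse rate (Hz).
#' @param width pulse width (ms).
#' @param amplitude signed amplitude (uA).
#' @param rate_end final pulse rate (Hz); defaults to `rate` (flat train).
#' @return A [stimulus_train()].
#' @export
rate_pulse_train <- function(t_on, duration, rate, width, amplitude,
                             rate_end = rate) {
  stopifnot(duration > 0, rate > 0, rate_end > 0)
  onsets <- numeric()
  t <- t_on
  while (t < t_on + duration) {
    onsets <- c(onsets, t)
    frac <- (t - t_on) / duration
    r <- rate + (rate_end - rate) * frac
    t <- t + 1000 / r
  }
  stimulus_train(onsets, width, amplitude)
}

#' Dendrite membrane-potential derivatives
#'
#' Node equations of the passive compartment chain: the stimulus current
#' enters compartment 1; interior compartments couple to both neighbours
#' through `R_a`; the last compartment couples only to its predecessor.
#'
#' @param v_m vector of compartment potentials (mV).
#' @param i_s instantaneous stimulus current (uA).
#' @param params a [dendrite_params()].
#' @return d(v_m)/dt in mV/ms.
#' @export
dendrite_derivatives <- function(v_m, i_s, params) {
  n <- params$n_compartments
  if (length(v_m) != n)
    stop("state length ", length(v_m), " does not match n_compartments ", n)
  leak <- -(v_m - params$V_TH) / params$R_EQ
  axial <- numeric(n)
  if (n > 1) {
    up <- (v_m[-n] - v_m[-1]) / params$R_a   # from compartment i to i+1
    axial[-1] <- axial[-1] + up
    axial[-n] <- axial[-n] - up
  }
  cur <- leak + axial
  cur[1] <- cur[1] + i_s
  cur / params$C_m
}

#' Simulate a passive dendrite
#'
#' Integrates the compartment chain with classic fixed-step RK4 from the
#' resting initial condition (all compartments at `V_TH`).
#'
#' @param stim a [stimulus_train()].
#' @param params a [dendrite_params()].
#' @param duration simulation length (ms).
#' @param dt integration step (ms).
#' @param record_dt sampling step of the returned traces (ms; a multiple
#'   of `dt`).
#' @return A list with `time` (ms) and `v_m` (matrix, time x compartment).
#' @export
simulate_dendrite <- function(stim, params, duration, dt = 0.01,
                              record_dt = dt) {
  stopifnot(duration > 0, dt > 0)
  record_every <- max(1L, as.integer(round(record_dt / dt)))
  pulses <- as.matrix(stim[, c("onset", "width", "amplitude")])
  storage.mode(pulses) <- "double"
  out <- cpp_simulate_dendrite(pulses, params, duration, dt, record_every)
  colnames(out$v_m) <- paste0("v_m", seq_len(params$n_compartments))
  out
}
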