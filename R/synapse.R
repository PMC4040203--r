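#' Synapse parameters
#'
#' The presynaptic terminal acts as a voltage-to-frequency converter: each
#' action potential is turned into one rectangular current pulse.  Pulse
#' width spans the interval during which the axonal potential exceeds the
#' detection level; the pulse is shifted by the axonal transmission delay;
#' its sign is a property of the connection (one neuron may excite one
#' target and inhibit another).
#'
#' @param pulse_amplitude pulse amplitude (uA, > 0).
#' @param detection_level axonal potential defining the pulse width (mV).
#' @param axonal_delay transmission delay between action potential and
#'   synaptic pulse (ms, >= 0).
#' @param sign +1 excitatory, -1 inhibitory.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(pulse_amplitude, detection_level = 0,
                           axonal_delay = 1, sign = 1) {
  stopifnot(pulse_amplitude > 0, axonal_delay >= 0, sign %in% c(-1, 1))
  structure(list(pulse_amplitude = pulse_amplitude,
                 detection_level = detection_level,
                 axonal_delay = axonal_delay, sign = sign),
            class = "synapse_params")
}

#' Convert an axonal potential trace into a synaptic pulse train
#'
#' Finds the upward and downward crossings of the detection level by
#' linear interpolation of the sampled trace and emits one pulse per
#' action potential: onset = upward crossing + axonal delay, width =
#' down-crossing minus up-crossing, amplitude = sign x pulse amplitude.
#' An action potential still above the detection level when the trace
#' ends is dropped with a warning.
#'
#' @param time sample times (ms).
#' @param V_m axonal membrane potential samples (mV).
#' @param params a [synapse_params()].
#' @return A [stimulus_train()].
#' @export
spikes_to_pulses <- function(time, V_m, params) {
  lev <- params$detection_level
  above <- V_m >= lev
  n <- length(V_m)
  if (n < 2 || !any(above))
    return(stimulus_train())
  idx_up <- which(!above[-n] & above[-1])
  idx_dn <- which(above[-n] & !above[-1])
  cross <- function(i) {
    f <- (lev - V_m[i]) / (V_m[i + 1] - V_m[i])
    time[i] + f * (time[i + 1] - time[i])
  }
  ups <- vapply(idx_up, cross, numeric(1))
  dns <- vapply(idx_dn, cross, numeric(1))
  # Pair each up-crossing with the first later down-crossing (a leading
  # unmatched down-crossing, trace starting above level, pairs with none).
  onsets <- widths <- numeric(0)
  for (u in ups) {
    d <- dns[dns > u]
    if (length(d) == 0) {
      warning("action potential still above detection level at series end; ",
              "event at t = ", signif(u, 6), " ms dropped")
      next
    }
    onsets <- c(onsets, u + params$axonal_delay)
    widths <- c(widths, d[1] - u)
  }
  stimulus_train(onsets, widths, params$sign * params$pulse_amplitude)
}
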