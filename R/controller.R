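#' Time-optimal controller parameters
#'
#' First-order low-pass filters convert motoneuron innervation into
#' active-state tension.  The agonist filter time constant switches from
#' the activation constant `tau_gac` (pulse, `t1 <= t < t2`) to the
#' deactivation constant `tau_gde` (slide/step, `t >= t2`); the antagonist
#' filter switches from the deactivation constant `tau_tde` (pause) to the
#' activation constant `tau_tac` at `t3`.  Before the latent period ends
#' (`t < t1`) both time constants are zero: tension tracks the fixation
#' innervation exactly.
#'
#' @param tau_gac,tau_gde agonist activation / deactivation time
#'   constants (ms, > 0).
#' @param tau_tde,tau_tac antagonist deactivation / activation time
#'   constants (ms, > 0).
#' @param t1 latent period end = saccade start (ms).
#' @param t2 agonist slide onset (ms, > t1).
#' @param t3 antagonist step onset (ms, > t1).
#' @return An object of class `controller_params`.
#' @export
controller_params <- function(tau_gac = 9, tau_gde = 7,
                              tau_tde = 5, tau_tac = 9,
                              t1 = 120, t2 = t1 + 56, t3 = t1 + 56) {
  stopifnot(tau_gac > 0, tau_gde > 0, tau_tde > 0, tau_tac > 0,
            t1 < t2, t1 < t3)
  structure(list(tau_gac = tau_gac, tau_gde = tau_gde, tau_tde = tau_tde,
                 tau_tac = tau_tac, t1 = t1, t2 = t2, t3 = t3),
            class = "controller_params")
}

filter_with_tau <- function(time, N, tau, F0) {
  stopifnot(length(time) == length(N), length(tau) == length(N))
  dt <- time[2] - time[1]
  cpp_filter_first_order(as.numeric(N), as.numeric(tau), F0, dt)
}

#' Agonist pulse-slide-step filter
#'
#' Exact (per zero-order-hold sample) first-order low-pass of the agonist
#' innervation with the piecewise time constant of the pulse-slide-step
#' controller.  Tension is continuous across the switches.
#'
#' @param time uniform sample times (ms).
#' @param N_ag agonist innervation samples (tension units, N).
#' @param params a [controller_params()].
#' @param F0 initial tension; defaults to `N_ag[1]` (fixation).
#' @return Vector of active-state tension `F_ag(t)`.
#' @export
agonist_filter <- function(time, N_ag, params, F0 = N_ag[1]) {
  tau <- ifelse(time < params$t1, 0,
                ifelse(time < params$t2, params$tau_gac, params$tau_gde))
  filter_with_tau(time, N_ag, tau, F0)
}

#' Antagonist pause-step filter
#'
#' First-order low-pass of the antagonist innervation with deactivation
#' constant `tau_tde` during the pause and activation constant `tau_tac`
#' from the step onset `t3`.
#'
#' @param time uniform sample times (ms).
#' @param N_ant antagonist innervation samples (N).
#' @param params a [controller_params()].
#' @param F0 initial tension; defaults to `N_ant[1]`.
#' @return Vector of active-state tension `F_ant(t)`.
#' @export
antagonist_filter <- function(time, N_ant, params, F0 = N_ant[1]) {
  tau <- ifelse(time < params$t1, 0,
                ifelse(time < params$t3, params$tau_tde, params$tau_tac))
  filter_with_tau(time, N_ant, tau, F0)
}

#' Fixation (steady-state) tensions for a target position
#'
#' During fixation the agonist and antagonist active-state tensions are
#' functions of eye position at steady state.  The required differential
#' tension is obtained from the plant equilibrium map (the linear solve of
#' the static muscle-fiber plant), and split between the two muscles by
#' the configured fraction `alpha`:
#' `F_ag = F_0 + alpha dF`, `F_ant = F_0 - (1 - alpha) dF`.
#' When the antagonist share would drive its tension negative (large
#' targets), the antagonist is clamped at zero and the agonist carries the
#' whole differential -- innervation cannot be negative.
#'
#' @param theta_target eye position (degrees, ipsilateral positive).
#' @param plant a [plant_params()] (element-level).
#' @param F_0 common fixation tension at the primary position (N).
#' @param alpha agonist share of the differential tension (0..1).
#' @return List with `F_ag`, `F_ant` (N) and the differential `dF`.
#' @export
steady_state_tensions <- function(theta_target, plant, F_0 = 0.14,
                                  alpha = 0.6) {
  g <- equilibrium_gain(plant, F_0, alpha)
  dF <- theta_target / g
  F_ag <- F_0 + alpha * dF
  F_ant <- F_0 - (1 - alpha) * dF
  if (F_ant < 0) {
    F_ant <- 0
    F_ag <- dF
  }
  if (F_ag < 0) {
    F_ag <- 0
    F_ant <- -dF
  }
  if (F_ag < 0 || F_ant < 0)
    stop("target position ", theta_target,
         " deg requires a negative fixation tension")
  list(F_ag = F_ag, F_ant = F_ant, dF = dF)
}

#' Tension program for inactive agonist fibers
#'
#' Agonist fibers that do not take part in the burst decay exponentially
#' during the pulse (time constant `tau_gac`) and rise back during the
#' slide (`tau_gde`), settling at the new fixation tension.  This is the
#' agonist filter applied to a pause-step innervation.
#'
#' @param time uniform sample times (ms).
#' @param params a [controller_params()].
#' @param F_fix0 fixation tension before the saccade (N).
#' @param F_fix_new fixation tension at the new position (N).
#' @return Vector of tension samples.
#' @export
inactive_fiber_program <- function(time, params, F_fix0, F_fix_new) {
  N <- ifelse(time < params$t1, F_fix0,
              ifelse(time < params$t2, 0, F_fix_new))
  agonist_filter(time, N, params, F0 = F_fix0)
}
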