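POPULATIONS <- c("LLBN", "OPN", "EBN", "IBN", "TN", "IN", "AN", "ON")

neuron_ids <- function() {
  c("OPN", as.vector(outer(setdiff(POPULATIONS, "OPN"), c("i", "c"),
                           paste, sep = "_")))
}

#' Build the two-sided saccadic burst generator network
#'
#' Assembles the parallel-distributed network: one midline omnipause
#' neuron (OPN) and one copy per side of each other population, the
#' signed synaptic wiring between them, and the scripted external drives
#' (contralateral superior colliculus, both fastigial nuclei, and the
#' vermis-timed termination gates) for an ipsilaterally directed saccade.
#'
#' Wiring per side (mirrored): the contralateral SC excites the ipsi LLBN
#' and EBN; the LLBN inhibits the OPN and excites the ipsi IBN; the OPN
#' inhibits EBN and IBN on both sides; the ipsi IBN inhibits the contra
#' EBN, TN and AN and the ipsi ON and IN; the ipsi EBN excites the ipsi
#' TN and AN; TN excites IN; IN excites AN; the ipsi AN excites the
#' contra ON.
#'
#' @param scenario a scenario name from the configuration table
#'   (`"4deg"`, ..., `"20deg"`) or a list with `burst_ms`, `n_active` and
#'   optionally `magnitude`.
#' @param config a [read_config()] configuration.
#' @return List of class `saccade_network` with `neurons` (per-id
#'   parameter blocks), `connections` (data frame), `drives` (per-id
#'   [stimulus_train()]s), `scenario`, and the planned event `times`.
#' @export
build_network <- function(scenario, config = default_config()) {
  sc <- scenario_row(config, scenario)
  ids <- neuron_ids()
  neurons <- lapply(ids, function(id) {
    pop <- sub("_[ic]$", "", id)
    neuron_params(config, pop)
  })
  names(neurons) <- ids

  # Signed wiring; one row per connection.
  wire <- function(src, tgt, sign) data.frame(source = src, target = tgt,
                                              sign = sign)
  side <- function(tmpl, s, o) {
    tmpl$source <- sub("_S$", paste0("_", s), tmpl$source)
    tmpl$source <- sub("_O$", paste0("_", o), tmpl$source)
    tmpl$target <- sub("_S$", paste0("_", s), tmpl$target)
    tmpl$target <- sub("_O$", paste0("_", o), tmpl$target)
    tmpl
  }
  tmpl <- rbind(
    wire("LLBN_S", "OPN", -1),
    wire("LLBN_S", "IBN_S", +1),
    wire("OPN", "EBN_S", -1),
    wire("OPN", "IBN_S", -1),
    wire("IBN_S", "EBN_O", -1),
    wire("IBN_S", "TN_O", -1),
    wire("IBN_S", "AN_O", -1),
    wire("IBN_S", "ON_S", -1),
    wire("IBN_S", "IN_S", -1),
    wire("EBN_S", "TN_S", +1),
    wire("EBN_S", "AN_S", +1),
    wire("TN_S", "IN_S", +1),
    wire("IN_S", "AN_S", +1),
    wire("AN_S", "ON_O", +1))
  conns <- unique(rbind(side(tmpl, "i", "c"), side(tmpl, "c", "i")))
  stopifnot(!any(conns$source == conns$target))
  dly <- config$connections$delays
  conns$delay_ms <- config$connections$default_delay_ms
  key <- paste0(conns$source, "->", conns$target)
  hit <- match(key, names(dly))
  conns$delay_ms[!is.na(hit)] <- unlist(dly)[hit[!is.na(hit)]]
  # pulse amplitude is set by the postsynaptic membrane: each connection
  # delivers the target population's tabulated amplitude, except where an
  # experimentally tuned per-connection override is configured
  amp <- vapply(conns$target, function(s)
    neurons[[s]]$synapse_amplitude, numeric(1))
  ovr <- config$connections$amplitudes
  hit2 <- match(key, names(ovr))
  amp[!is.na(hit2)] <- unlist(ovr)[hit2[!is.na(hit2)]]
  conns$amplitude <- amp * conns$sign

  # Scripted drives.  The planned saccade spans [t1, t_end]; the planned
  # end folds in the per-scenario termination calibration (the cerebellar
  # terminator anticipates the realized saccade end).
  t1 <- config$scenarios$latent_ms
  t_end <- t1 + sc$burst_ms + sc$end_cal_ms
  dr <- config$drives
  drives <- setNames(vector("list", length(ids)), ids)
  sc_mk <- function(amp) rate_pulse_train(
    t1 - dr$sc$lead_ms,
    (t_end + dr$sc$end_offset_ms) - (t1 - dr$sc$lead_ms),
    dr$sc$rate_peak, dr$sc$width_ms, amp, rate_end = dr$sc$rate_end)
  sc_train <- sc_mk(dr$sc$amplitude)
  sc_ebn <- sc_mk(if (is.null(dr$sc$amplitude_ebn)) dr$sc$amplitude
                  else dr$sc$amplitude_ebn)
  fnc <- dr$fn_contra
  fnc_mk <- function(amp) rate_pulse_train(
    t1 - fnc$lead_ms, (t_end + fnc$end_offset_ms) - (t1 - fnc$lead_ms),
    fnc$rate, fnc$width_ms, amp)
  fnc_train <- fnc_mk(fnc$amplitude)
  fnc_ebn <- fnc_mk(if (is.null(fnc$amplitude_ebn)) fnc$amplitude
                    else fnc$amplitude_ebn)
  fni <- dr$fn_ipsi
  fni_train <- rate_pulse_train(t_end + fni$onset_offset_ms,
                                fni$duration_ms, fni$rate, fni$width_ms,
                                fni$amplitude)
  add_drive <- function(id, train) {
    drives[[id]] <<- if (is.null(drives[[id]])) train else {
      st <- rbind(drives[[id]], train)
      st[order(st$onset), ]
    }
  }
  add_drive("LLBN_i", sc_train)
  add_drive("EBN_i", sc_ebn)
  add_drive("LLBN_i", fnc_train)
  add_drive("EBN_i", fnc_ebn)
  add_drive("IBN_i", fnc_train)
  add_drive("EBN_c", fni_train)   # end burst gates the contra MLBN;
  add_drive("IBN_c", fni_train)   # the contra LLBN is left undriven so
                                  # the OPN can resume at the saccade end
  if (!is.null(dr$opn_tonic) && dr$opn_tonic$amplitude > 0)
    add_drive("OPN", stimulus_train(0, 1e7, dr$opn_tonic$amplitude))
  # fixation re-engagement at the saccade end snaps the OPN out of its
  # hyperpolarized pause (the resumption the cerebellar vermis times)
  if (!is.null(dr$opn_resume) && dr$opn_resume$amplitude > 0)
    add_drive("OPN", stimulus_train(t_end + dr$opn_resume$offset_ms,
                                    dr$opn_resume$duration_ms,
                                    dr$opn_resume$amplitude))

  structure(list(neurons = neurons, connections = conns, drives = drives,
                 scenario = sc,
                 times = list(t1 = t1, t_end = t_end,
                              burst_ms = sc$burst_ms)),
            class = "saccade_network")
}

#' Simulate the coupled circuit
#'
#' Integrates every neuron (passive dendrite chain plus Hodgkin-Huxley
#' axon or FitzHugh-Nagumo oscillator) with current-pulse synaptic
#' coupling: each connection delivers `sign x amplitude` microamps to its
#' target's first dendrite compartment whenever the delayed presynaptic
#' potential exceeds the source's detection level, so pulse widths span
#' the action potentials and onsets trail them by the axonal delay.
#'
#' @param network a [build_network()] result.
#' @param duration total simulated time (ms); defaults to the planned
#'   saccade end plus the configured fixation tail.
#' @param config the configuration (for integration steps).
#' @return List of class `saccade_simulation` with the trace time grid,
#'   per-neuron dendritic and axonal potentials, spike times, detection
#'   crossings, and integrator traces.
#' @export
simulate_circuit <- function(network, duration = NULL,
                             config = default_config()) {
  ids <- names(network$neurons)
  dt <- config$sim$dt_ms
  rec <- config$sim$record_dt_ms
  warm <- if (is.null(config$sim$warmup_ms)) 0 else config$sim$warmup_ms
  if (is.null(duration))
    duration <- network$times$t_end + config$sim$post_ms
  nrn <- lapply(network$neurons, function(np) {
    out <- list(dendrite = np$dendrite, model = np$model,
                detection_level = np$detection_level)
    if (np$model == "hh") out$axon <- np$axon else out$oscillator <-
        np$oscillator
    out
  })
  conn <- cbind(match(network$connections$source, ids) - 1L,
                match(network$connections$target, ids) - 1L,
                as.integer(round(network$connections$delay_ms / dt)))
  storage.mode(conn) <- "integer"
  drv <- lapply(ids, function(id) {
    tr <- network$drives[[id]]
    if (is.null(tr)) matrix(numeric(0), 0, 3) else {
      m <- as.matrix(tr[, c("onset", "width", "amplitude")])
      m[, 1] <- m[, 1] + warm      # shift drives past the warm-up
      storage.mode(m) <- "double"
      m
    }
  })
  out <- cpp_simulate_circuit(nrn, conn, network$connections$amplitude,
                              drv, duration + warm, dt,
                              as.integer(round(rec / dt)))
  # drop the warm-up (tonic units charging their accumulators to the
  # fixation baseline) and restore the nominal time origin
  keep <- out$time >= warm
  time <- out$time[keep] - warm
  shift <- function(v) { v <- v[v >= warm] - warm; v }
  structure(list(time = time,
                 V_axon = `colnames<-`(out$V_axon[keep, , drop = FALSE],
                                       ids),
                 V_dendrite = `colnames<-`(
                   out$V_dendrite[keep, , drop = FALSE], ids),
                 acc = `colnames<-`(out$acc[keep, , drop = FALSE], ids),
                 spikes = setNames(lapply(out$ups, shift), ids),
                 downs = setNames(lapply(out$downs, shift), ids),
                 network = network, dt = rec),
            class = "saccade_simulation")
}

#' Instantaneous firing rate from a spike train
#'
#' Reciprocal interspike interval, sample-and-hold between consecutive
#' spikes (zero where no pair of spikes brackets the sample), optionally
#' smoothed with a centred moving average.
#'
#' @param spikes sorted spike times (ms).
#' @param time sample times (ms, uniform).
#' @param smooth_ms moving-average window (ms; 0 disables smoothing).
#' @return Rate samples in Hz.
#' @export
extract_rate_signal <- function(spikes, time, smooth_ms = 0) {
  rate <- numeric(length(time))
  if (length(spikes) >= 2) {
    isi <- diff(spikes)
    idx <- findInterval(time, spikes)
    inside <- idx >= 1 & idx < length(spikes)
    rate[inside] <- 1000 / isi[idx[inside]]
  }
  if (smooth_ms > 0 && length(time) > 1) {
    w <- max(1L, as.integer(round(smooth_ms / (time[2] - time[1]))))
    if (w > 1) {
      k <- rep(1 / w, w)
      rate <- as.numeric(stats::filter(rate, k, sides = 2))
      rate[is.na(rate)] <- 0
    }
  }
  rate
}

# indices of spikes inside [a, b] that belong to a burst (interspike
# interval to a neighbour below isi_max)
win_spikes <- function(sp, a, b, isi_max) {
  inw <- which(sp >= a & sp <= b)
  if (length(inw) < 2) return(integer())
  d <- diff(sp[inw])
  keep <- c(d[1] <= isi_max, pmin(d, c(d[-1], Inf)) <= isi_max)
  inw[keep]
}

#' Motoneuron innervation commands in tension units
#'
#' Converts the motoneuron firing rates of one side into agonist and
#' antagonist innervation signals for the controller.  Tonic rates map
#' through an affine transformation calibrated per run: the pre-saccadic
#' tonic rate maps to the fixation tension at the initial position and
#' the post-saccadic tonic rate to the fixation tension at the target
#' (both obtained from the plant-equilibrium map), which is how a tonic
#' firing rate is scaled to an active-state tension.  On top of the tonic
#' map, the saturated burst regime (agonist rate above `burst_rate_hz`)
#' commands the configured pulse tension, and the saccadic pause
#' (antagonist rate below `pause_rate_hz`) commands zero.
#'
#' @param sim a [simulate_circuit()] result.
#' @param side `"i"` (right eye: agonist = ipsi AN, antagonist = ipsi ON)
#'   or `"c"` (left eye: agonist = contra ON, antagonist = contra AN).
#' @param config the configuration.
#' @param theta_target target amplitude (degrees); defaults to the
#'   scenario magnitude.
#' @return List with `time`, `N_ag`, `N_ant`, the rate traces, the
#'   calibration, and the fixation tensions used.
#' @export
motoneuron_commands <- function(sim, side = "i",
                                config = default_config(),
                                theta_target = NULL) {
  net <- sim$network
  if (is.null(theta_target)) theta_target <- net$scenario$magnitude
  cc <- config$controller
  t1 <- net$times$t1
  t_end <- net$times$t_end
  ag_id <- if (side == "i") "AN_i" else "ON_c"
  ant_id <- if (side == "i") "ON_i" else "AN_c"
  time <- sim$time
  r_ag <- extract_rate_signal(sim$spikes[[ag_id]], time, cc$rate_smooth_ms)
  r_ant <- extract_rate_signal(sim$spikes[[ant_id]], time,
                               cc$rate_smooth_ms)
  pp <- plant_from_config(config)
  F0 <- cc$fixation_F0_N
  ss0 <- steady_state_tensions(0, pp, F0, cc$agonist_share)
  ssT <- steady_state_tensions(theta_target, pp, F0, cc$agonist_share)

  win_pre <- time >= t1 - 60 & time <= t1 - 30
  win_post <- time >= t_end + 80 & time <= t_end + 180
  # Tonic units have no spike pair bracketing the very ends of the trace;
  # hold the nearest measured tonic rate there instead of reading zero.
  patch_ends <- function(rate, rp, rq) {
    nz <- which(rate > 0)
    if (!length(nz)) return(rate)
    if (nz[1] > 1) rate[seq_len(nz[1] - 1)] <- rp
    if (nz[length(nz)] < length(rate))
      rate[(nz[length(nz)] + 1):length(rate)] <- rq
    rate
  }
  cal <- function(rate, F_pre, F_post) {
    r_pre <- mean(rate[win_pre])
    r_post <- mean(rate[win_post])
    dr <- r_post - r_pre
    if (abs(dr) < cc$min_rate_delta_hz)
      dr <- sign(dr + 1e-12) * cc$min_rate_delta_hz
    slope <- (F_post - F_pre) / dr
    list(r_pre = r_pre, r_post = r_post, slope = slope,
         intercept = F_pre - slope * r_pre)
  }
  cal_ag <- cal(r_ag, ss0$F_ag, ssT$F_ag)
  cal_ant <- cal(r_ant, ss0$F_ant, ssT$F_ant)
  r_ag <- patch_ends(r_ag, cal_ag$r_pre, cal_ag$r_post)
  r_ant <- patch_ends(r_ant, cal_ant$r_pre, cal_ant$r_post)

  # The tonic affine map only applies in the tonic regime; the burst is
  # the saturated pulse and the transition ramps (an artifact of rate
  # smoothing) are folded into it.  Tension commands are bounded by the
  # largest fixation tension so mid-transition rate samples cannot
  # command unphysical tensions.
  # The affine transformation maps tonic rates; rate samples outside the
  # calibrated tonic band (burst ramps, pause ramps) are clamped to its
  # ends so the map is never extrapolated.
  band <- function(rate, cal) pmin(max(cal$r_pre, cal$r_post),
                                   pmax(min(cal$r_pre, cal$r_post), rate))
  cap_ag <- 1.1 * max(ss0$F_ag, ssT$F_ag)
  N_ag <- pmin(cap_ag, pmax(0, cal_ag$intercept +
                                 cal_ag$slope * band(r_ag, cal_ag)))
  win_sac <- time >= t1 - 30 & time <= t_end + 10
  rmax <- max(r_ag[win_sac])
  if (rmax > cc$burst_rate_hz) {
    r_lo <- cal_ag$r_pre + 0.25 * (rmax - cal_ag$r_pre)
    # the saturated pulse spans the actual burst spikes; smoothing spreads
    # the rate trace a few ms beyond them on either side
    sp_ag <- sim$spikes[[ag_id]]
    # burst spikes: interspike intervals well below the tonic interval
    # (the burst tapers as the excitatory drive decays, so the criterion
    # is looser than the saturated-burst rate)
    isi_burst <- 2000 / cc$burst_rate_hz
    bsp <- sp_ag[win_spikes(sp_ag, t1 - 30, t_end + 10, isi_burst)]
    # the pulse spans from the first burst spike to the end of the
    # agonist burst interval (the command stays saturated while the
    # motoneuron burst tapers; the slide takes over at the interval end)
    t2 <- t1 + net$times$burst_ms
    burst_mask <- time >= min(bsp) & time < pmax(max(bsp), t2)
    N_ag[burst_mask] <- cc$pulse_N
    # before the burst the agonist is at its fixation innervation; the
    # interval-reciprocal rate is unreliable across the last tonic ISI
    N_ag[time < min(time[burst_mask])] <- ss0$F_ag
  }
  cap_ant <- 1.1 * max(ss0$F_ant, ssT$F_ant)
  N_ant <- pmin(cap_ant, pmax(0, cal_ant$intercept +
                                   cal_ant$slope * band(r_ant, cal_ant)))
  # The saccadic pause is detected causally from the spike train itself
  # (no spike for 1.4 baseline intervals); the interval-reciprocal rate
  # trace would otherwise backdate the pause to the last tonic spike.
  sp_ant <- sim$spikes[[ant_id]]
  t_since <- time - sp_ant[pmax(1L, findInterval(time, sp_ant))]
  t_since[time < sp_ant[1]] <- 0
  isi0 <- 1000 / max(cal_ant$r_pre, 1)
  silent <- win_sac & t_since > 1.4 * isi0
  # a pause can only be confirmed after more than one baseline interval
  # without a spike; once confirmed, backdate its onset to the unbiased
  # estimate (half an interval past the last spike)
  dt_s <- time[2] - time[1]
  back <- as.integer(round(0.9 * isi0 / dt_s))
  starts <- which(silent & !c(FALSE, silent[-length(silent)]))
  for (s in starts)
    silent[max(1, s - back):s] <- TRUE
  N_ant[silent] <- 0
  if (any(silent))   # fixation innervation holds until the pause begins
    N_ant[time < min(time[silent])] <- ss0$F_ant

  list(time = time, N_ag = N_ag, N_ant = N_ant, rate_ag = r_ag,
       rate_ant = r_ant, cal_ag = cal_ag, cal_ant = cal_ant,
       F_fix0 = list(ag = ss0$F_ag, ant = ss0$F_ant),
       F_fixT = list(ag = ssT$F_ag, ant = ssT$F_ant))
}

#' Burst and pause event times of every population
#'
#' Detects, per neuron, the first sustained departure from (and return
#' to) its baseline firing around the saccade: for burst neurons the
#' burst onset/offset, for the omnipause neuron the pause onset/offset,
#' and for tonic units the silencing window, using interspike-interval
#' gaps relative to the pre-saccadic baseline.
#'
#' @param sim a [simulate_circuit()] result.
#' @return Data frame with neuron, event (`burst`/`pause`), onset and
#'   offset times (ms; `NA` when the neuron shows no such event).
#' @export
population_events <- function(sim) {
  net <- sim$network
  t1 <- net$times$t1
  rows <- NULL
  for (id in names(sim$spikes)) {
    sp <- sim$spikes[[id]]
    base <- sp[sp < t1 - 40]
    baseline_rate <- if (length(base) >= 2)
      1000 * (length(base) - 1) / diff(range(base)) else 0
    if (baseline_rate < 10) {
      # silent at rest: burst = first/last spikes of the saccade window
      sp_win <- sp[sp > t1 - 40 & sp < net$times$t_end + 60]
      rows <- rbind(rows, data.frame(
        neuron = id, event = "burst",
        onset = if (length(sp_win)) min(sp_win) else NA_real_,
        offset = if (length(sp_win)) max(sp_win) else NA_real_))
    } else {
      # tonically active: pause = largest interspike gap near the saccade
      sp_win <- sp[sp > t1 - 60 & sp < net$times$t_end + 80]
      if (length(sp_win) >= 2) {
        gaps <- diff(sp_win)
        g <- which.max(gaps)
        base_isi <- 1000 / baseline_rate
        if (gaps[g] > 4 * base_isi) {
          rows <- rbind(rows, data.frame(neuron = id, event = "pause",
                                         onset = sp_win[g],
                                         offset = sp_win[g + 1]))
          next
        }
      }
      rows <- rbind(rows, data.frame(neuron = id, event = "pause",
                                     onset = NA_real_, offset = NA_real_))
    }
  }
  rows
}
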