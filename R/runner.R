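#' Run a complete saccade simulation
#'
#' End-to-end pipeline: build the network for the scenario, simulate the
#' spiking circuit, convert motoneuron firing into innervation commands,
#' low-pass them into per-fiber active-state tensions (active fibers get
#' the burst command, the remaining agonist fibers the decay/rise
#' program, antagonist fibers the pause-step), and integrate the
#' muscle-fiber plant.  Everything is deterministic for a fixed
#' configuration.
#'
#' @param scenario scenario name (`"4deg"`, `"8deg"`, `"12deg"`,
#'   `"16deg"`, `"20deg"`) or list with `burst_ms`, `n_active`, and
#'   optionally `magnitude`.
#' @param config a [read_config()] configuration.
#' @param out_dir optional directory for trace/summary exports.
#' @param keep_sim keep the full circuit simulation object in the result.
#' @return List of class `saccade_run`: scenario, `time`, `theta`,
#'   `theta_dot`, `T_ag`, `T_ant`, tension traces, commands, saccade
#'   `metrics`, population `events`, and the configuration fingerprint.
#' @export
run_saccade <- function(scenario, config = default_config(),
                        out_dir = NULL, keep_sim = FALSE) {
  net <- build_network(scenario, config)
  sc <- net$scenario
  sim <- simulate_circuit(net, config = config)
  cmd <- motoneuron_commands(sim, "i", config)
  cp <- controller_from_config(config, sc$burst_ms)
  pp <- plant_from_config(config)
  m <- config$plant$m
  n_active <- sc$n_active
  stopifnot(n_active >= 0, n_active <= m)

  time <- cmd$time
  F_active <- agonist_filter(time, cmd$N_ag, cp, F0 = cmd$F_fix0$ag)
  F_inactive <- inactive_fiber_program(time, cp, cmd$F_fix0$ag,
                                       cmd$F_fixT$ag)
  F_ant <- antagonist_filter(time, cmd$N_ant, cp, F0 = cmd$F_fix0$ant)
  if (n_active == 0 || sc$magnitude == 0) {
    # no saccade command: every fiber keeps its fixation tension
    F_active <- rep(cmd$F_fix0$ag, length(time))
    F_inactive <- F_active
    F_ant <- rep(cmd$F_fix0$ant, length(time))
  }
  grp <- c(rep(1L, n_active), rep(2L, m - n_active))
  plant <- simulate_plant(time, cbind(F_active, F_inactive), grp, F_ant,
                          pp)
  thr <- config$plant$velocity_threshold_deg_s
  metrics <- saccade_metrics(time, plant$theta, plant$theta_dot,
                             threshold = thr)
  events <- population_events(sim)
  run <- structure(list(
    scenario = sc, time = time, theta = plant$theta,
    theta_dot = plant$theta_dot, T_ag = plant$T_ag, T_ant = plant$T_ant,
    F_active = F_active, F_inactive = F_inactive, F_ant = F_ant,
    commands = cmd, metrics = metrics, events = events,
    times = net$times, spikes = sim$spikes,
    config_fingerprint = config_fingerprint(config)),
    class = "saccade_run")
  if (keep_sim) run$sim <- sim
  if (!is.null(out_dir)) export_run(run, out_dir)
  run
}

#' Eye position at a fixed time after saccade onset
#'
#' @param run a [run_saccade()] result.
#' @param after_ms measurement time relative to the planned saccade onset
#'   (latent-period end).
#' @return Eye position in degrees.
#' @export
final_position <- function(run, after_ms = 200) {
  t_meas <- run$times$t1 + after_ms
  run$theta[which.min(abs(run$time - t_meas))]
}

#' Main-sequence table over the scenario set
#'
#' Runs every scenario in the configuration table and collects magnitude,
#' duration and peak velocity (the main-sequence measures), plus the
#' realized final position.
#'
#' @param config a [read_config()] configuration.
#' @param out_dir optional export directory (writes
#'   `main_sequence.csv`).
#' @return Data frame with one row per scenario; errors in individual
#'   scenarios are collected in attribute `errors`.
#' @export
main_sequence <- function(config = default_config(), out_dir = NULL) {
  rows <- NULL; errs <- list()
  for (sc in config$scenarios$table) {
    res <- tryCatch(run_saccade(sc$name, config), error = function(e) e)
    if (inherits(res, "error")) { errs[[sc$name]] <- res; next }
    rows <- rbind(rows, data.frame(
      scenario = sc$name, magnitude_deg = sc$magnitude,
      burst_ms = sc$burst_ms, n_active = sc$n_active,
      duration_ms = res$metrics$duration_ms,
      peak_velocity_deg_s = res$metrics$peak_velocity_deg_s,
      final_deg = final_position(res)))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rows, file.path(out_dir, "main_sequence.csv"),
              row.names = FALSE)
  }
  attr(rows, "errors") <- errs
  rows
}

#' Export the three-panel demonstration traces for one population
#'
#' Runs the 16 degree reference scenario and writes, for the requested
#' (ipsilateral) population, its dendritic membrane potential, axonal
#' membrane potential, and synaptic output pulse train.
#'
#' @param population one of `LLBN`, `OPN`, `EBN`, `IBN`, `TN`, `IN`,
#'   `AN`, `ON`.
#' @param config a [read_config()] configuration.
#' @param out_dir optional export directory.
#' @return List with `time`, `v_dendrite`, `v_axon`, `pulses` (a
#'   [stimulus_train()]), and `spikes`.
#' @export
neuron_demo <- function(population, config = default_config(),
                        out_dir = NULL) {
  if (!population %in% POPULATIONS)
    stop("unknown population '", population, "'; one of ",
         paste(POPULATIONS, collapse = ", "))
  net <- build_network("16deg", config)
  sim <- simulate_circuit(net, config = config)
  id <- if (population == "OPN") "OPN" else paste0(population, "_i")
  np <- net$neurons[[id]]
  delay <- config$connections$default_delay_ms
  sp <- synapse_params(np$synapse_amplitude,
                       detection_level = np$detection_level,
                       axonal_delay = delay, sign = 1)
  pulses <- spikes_to_pulses(sim$time, sim$V_axon[, id], sp)
  out <- list(time = sim$time, v_dendrite = sim$V_dendrite[, id],
              v_axon = sim$V_axon[, id], pulses = pulses,
              spikes = sim$spikes[[id]], neuron = id,
              events = population_events(sim))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(time_ms = out$time,
                         v_dendrite_mV = out$v_dendrite,
                         v_axon_mV = out$v_axon),
              file.path(out_dir, paste0(id, "_trace.csv")),
              row.names = FALSE)
    write.csv(data.frame(connection_id = id,
                         onset_ms = out$pulses$onset,
                         width_ms = out$pulses$width,
                         amplitude_uA = out$pulses$amplitude),
              file.path(out_dir, paste0(id, "_pulses.csv")),
              row.names = FALSE)
  }
  out
}

export_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(time_ms = run$time, theta_deg = run$theta,
                       theta_dot_deg_s = run$theta_dot,
                       T_ag_N = run$T_ag, T_ant_N = run$T_ant),
            file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  spk <- do.call(rbind, lapply(names(run$spikes), function(id) {
    s <- run$spikes[[id]]
    if (!length(s)) return(NULL)
    data.frame(neuron_id = id, spike_time_ms = s)
  }))
  write.csv(spk, file.path(out_dir, "spikes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(scenario = run$scenario, metrics = run$metrics,
         final_deg = final_position(run),
         config_fingerprint = run$config_fingerprint),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$events, file.path(out_dir, "events.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Peak firing rate of an isolated population under sustained drive
#'
#' Builds one neuron (dendrite plus spike generator) from the
#' configuration, drives its dendrite with a sustained suprathreshold
#' pulse train, and reports the peak instantaneous firing rate as the
#' reciprocal of the minimum interspike interval.
#'
#' @param population population name (default the excitatory burst
#'   neuron, whose calibrated peak approaches 1 kHz).
#' @param config a [read_config()] configuration.
#' @param duration drive duration (ms).
#' @param spike_level spike detection level (mV).
#' @return List with `peak_rate_hz`, `spikes`, and the drive used.
#' @export
burst_peak_rate <- function(population = "EBN",
                            config = default_config(), duration = 100,
                            spike_level = 0) {
  np <- neuron_params(config, population)
  if (np$model != "hh")
    stop("peak-rate protocol applies to spiking (HH) populations")
  dd <- config$drives$ebn_demo
  st <- rate_pulse_train(0, duration, dd$rate, dd$width_ms, dd$amplitude)
  dt <- config$sim$dt_ms
  rec <- config$sim$record_dt_ms
  d <- simulate_dendrite(st, np$dendrite, duration, dt = rec)
  v_last <- d$v_m[, np$dendrite$n_compartments]
  Im <- rep(np$axon$gain_in *
              (v_last[-length(v_last)] - np$dendrite$V_TH) /
              np$dendrite$R_a, each = as.integer(round(rec / dt)))
  ax <- simulate_axon(Im, np$axon, dt = dt, spike_level = spike_level)
  isi <- diff(ax$spikes)
  list(peak_rate_hz = if (length(isi)) 1000 / min(isi) else 0,
       spikes = ax$spikes, n_spikes = length(ax$spikes),
       drive = st)
}
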