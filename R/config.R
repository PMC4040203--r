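#' Load a simulation configuration
#'
#' Reads a hierarchical YAML configuration (neuron membrane tables, drive
#' choreography, controller constants, plant mechanics, scenario table).
#' Values missing from `path` are filled from the packaged defaults, so a
#' user file only needs the keys it overrides.
#'
#' @param path path to a YAML file, or `NULL` for the packaged defaults.
#' @return A nested configuration list of class `saccade_config`.
#' @export
read_config <- function(path = NULL) {
  def <- yaml::read_yaml(system.file("extdata", "default-config.yaml",
                                     package = "saccadegen"))
  cfg <- if (is.null(path)) def else {
    user <- yaml::read_yaml(path)
    merge_lists(def, user)
  }
  structure(cfg, class = c("saccade_config", "list"))
}

#' @rdname read_config
#' @export
default_config <- function() read_config(NULL)

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Write a configuration to YAML
#'
#' @param config a `saccade_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Reproducible configuration fingerprint
#'
#' FNV-1a hash (32 bit, hex) over the canonical serialization of the
#' configuration: identical fingerprints imply identical inputs, so a run
#' report can be traced back to its exact configuration.
#'
#' @param config a `saccade_config` (any R object works).
#' @return An 8-character hex string.
#' @export
config_fingerprint <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  # skip the serialization header (carries the writing R version)
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), b)   # xor touches the low byte only
    # 32-bit multiply (lo + hi * 2^16) * 16777619 mod 2^32, in doubles
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

scenario_row <- function(config, scenario) {
  tab <- config$scenarios$table
  names(tab) <- vapply(tab, `[[`, "", "name")
  if (is.character(scenario)) {
    if (!scenario %in% names(tab))
      stop("unknown scenario '", scenario, "'; known: ",
           paste(names(tab), collapse = ", "))
    return(tab[[scenario]])
  }
  stopifnot(is.list(scenario), !is.null(scenario$burst_ms),
            !is.null(scenario$n_active))
  if (is.null(scenario$name)) scenario$name <- "custom"
  if (is.null(scenario$magnitude))
    scenario$magnitude <- amplitude_from_burst(config, scenario$burst_ms,
                                               scenario$n_active)
  if (is.null(scenario$end_cal_ms)) scenario$end_cal_ms <- 2.5
  scenario
}

#' Saccade amplitude implied by burst duration and active-fiber count
#'
#' For custom scenarios without a stated magnitude, the target amplitude
#' is interpolated from the scenario table with the time-optimal coding
#' model `magnitude = (n_active / m) * (a0 + a1 * burst)`, fitted once by
#' least squares to the five tabulated scenarios.  With no active fibers
#' the amplitude is zero (no saccade command).
#'
#' @param config a `saccade_config`.
#' @param burst_ms agonist burst duration (ms).
#' @param n_active number of active agonist fibers.
#' @return Amplitude in degrees.
#' @export
amplitude_from_burst <- function(config, burst_ms, n_active) {
  tab <- do.call(rbind, lapply(config$scenarios$table, as.data.frame))
  m <- config$plant$m
  frac <- tab$n_active / m
  fit <- lm(I(magnitude / frac) ~ burst_ms, data = transform(tab, frac = frac))
  as.numeric((n_active / m) *
               (coef(fit)[1] + coef(fit)[2] * burst_ms))
}

#' Assemble per-population model parameters from the configuration
#'
#' @param config a `saccade_config`.
#' @param pop population name (`LLBN`, `OPN`, `EBN`, `IBN`, `TN`, `IN`,
#'   `AN`, `ON`).
#' @return List with `dendrite` ([dendrite_params()]), `model`
#'   (`"hh"`/`"fhn"`), `axon` or `oscillator`, and `synapse` parameters.
#' @export
neuron_params <- function(config, pop) {
  nc <- config$neurons
  if (!pop %in% names(nc)) stop("unknown population '", pop, "'")
  blk <- nc[[pop]]
  com <- nc$common
  den <- dendrite_params(com$n_compartments, blk$dendrite$C_m,
                         blk$dendrite$R_EQ, com$R_a_kohm, com$V_TH_mV)
  out <- list(population = pop, dendrite = den)
  if (!is.null(blk$oscillator)) {
    out$model <- "fhn"
    out$oscillator <- do.call(fhn_params, c(
      blk$oscillator[c("a", "b", "eps", "timescale")],
      list(I_base = blk$oscillator$I_base,
           gain_dendrite = blk$oscillator$gain_dendrite,
           gain_integrator = blk$oscillator$gain_integrator,
           w_inhibitory = blk$oscillator$w_inhibitory,
           tau_leak = if (is.null(blk$oscillator$tau_leak)) 0
                      else blk$oscillator$tau_leak)))
    out$detection_level <- blk$synapse$detection_level
  } else {
    out$model <- "hh"
    out$axon <- hh_params(blk$axon$variant,
                          rate_coefficient = blk$axon$coefficient,
                          gain_in = blk$axon$gain_in)
    out$detection_level <- if (!is.null(blk$synapse$detection_level))
      blk$synapse$detection_level else com$detection_level_mV
  }
  out$synapse_amplitude <- blk$synapse$amplitude
  out
}

#' Element-level plant parameters from the configuration
#'
#' @param config a `saccade_config`.
#' @return A [plant_params()] at the fiber level.
#' @export
plant_from_config <- function(config) {
  pc <- config$plant
  fiber_parameter_scaling(
    list(K_se = pc$K_se, B_2 = pc$B_2, K_lt = pc$K_lt, B_1 = pc$B_1,
         J_p = pc$J_p, B_p = pc$B_p, K_p = pc$K_p, r = pc$r_m,
         stretch = pc$stretch_m),
    n = pc$n, m = pc$m)
}

controller_from_config <- function(config, burst_ms) {
  cc <- config$controller
  t1 <- cc$latent_ms
  # motoneuron bursts lead the movement; the activation regime engages
  # with them, slightly before the nominal latent-period end
  lead <- if (is.null(cc$activation_lead_ms)) 10 else cc$activation_lead_ms
  controller_params(cc$tau_gac_ms, cc$tau_gde_ms, cc$tau_tde_ms,
                    cc$tau_tac_ms, t1 = t1 - lead, t2 = t1 + burst_ms,
                    t3 = t1 + burst_ms)
}
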