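# Default configuration: parametric realization of the eight neuron
# populations (dendrite / axon / synapse per population), the scripted
# collicular and cerebellar drives, the time-optimal controller, and the
# muscle-fiber oculomotor plant.  Dendrite capacitances (uF), resistances
# (kOhm) and synaptic pulse amplitudes (uA) follow the published membrane
# table; axon gating-rate coefficients and dendro-axonal gains are the
# package's calibrated values that realize the published peak firing
# rates under this implementation (the published coefficient column is
# kept in `coefficient_printed` for reference).
sim:
  dt_ms: 0.001          # integration step of the spiking network
  record_dt_ms: 0.01    # trace sampling step (shared with the plant)
  warmup_ms: 300        # pre-roll letting tonic units reach fixation baseline
  post_ms: 260          # simulated fixation after the planned saccade end
neurons:
  common:
    n_compartments: 14
    R_a_kohm: 0.1
    V_TH_mV: -60
    detection_level_mV: 0
  LLBN:
    dendrite: {C_m: 0.5, R_EQ: 3.75}
    axon: {variant: basic, coefficient: 6, coefficient_printed: 18000,
           gain_in: 2.0, threshold_mV: -45}
    synapse: {amplitude: 20, detection_level: -10}
  OPN:
    dendrite: {C_m: 1.0, R_EQ: 6.3}
    axon: {variant: modified, coefficient: 2.2, coefficient_printed: 1800,
           gain_in: 2.5, threshold_mV: -60}
    synapse: {amplitude: 45, detection_level: -45}
  EBN:
    dendrite: {C_m: 0.45, R_EQ: 3.1}
    axon: {variant: modified, coefficient: 10, coefficient_printed: 35000,
           gain_in: 3.0, threshold_mV: -60}
    synapse: {amplitude: 75, detection_level: -20}
  IBN:
    dendrite: {C_m: 0.35, R_EQ: 4.5}
    axon: {variant: basic, coefficient: 6, coefficient_printed: 15000,
           gain_in: 2.5, threshold_mV: -45}
    synapse: {amplitude: 65, detection_level: -25}
  AN:
    dendrite: {C_m: 0.35, R_EQ: 5.5}
    axon: {variant: basic, coefficient: 5, coefficient_printed: 17000,
           gain_in: 0.5, threshold_mV: -45}
    synapse: {amplitude: 55}
  "ON":
    dendrite: {C_m: 0.45, R_EQ: 4.0}
    axon: {variant: basic, coefficient: 5, coefficient_printed: 17000,
           gain_in: 3.0, threshold_mV: -45}
    synapse: {amplitude: 55}
  TN:
    dendrite: {C_m: 0.35, R_EQ: 4.5}
    oscillator: {a: 0.7, b: 0.8, eps: 0.08, timescale: 4, I_base: 0.42,
                 gain_dendrite: 0.02, gain_integrator: 1.6e-3,
                 w_inhibitory: 1}
    synapse: {amplitude: 10, detection_level: 1.3}
  IN:
    dendrite: {C_m: 0.4, R_EQ: 4.5}
    oscillator: {a: 0.7, b: 0.8, eps: 0.08, timescale: 4, I_base: -3.2,
                 gain_dendrite: 1.5, gain_integrator: 0.0143,
                 w_inhibitory: 0, tau_leak: 100}
    synapse: {amplitude: 10, detection_level: 1.5}
connections:
  default_delay_ms: 1.0
  # per-connection delay overrides, keyed "SRC->TGT" with sides
  delays:
    "LLBN_i->OPN": 3.0
    "LLBN_c->OPN": 3.0
  # experimentally tuned per-connection pulse-amplitude overrides (uA)
  amplitudes:
    "IBN_i->IN_i": 60
    "IBN_c->IN_c": 60
    "EBN_i->AN_i": 110
    "EBN_c->AN_c": 110
    "LLBN_i->IBN_i": 14
    "LLBN_c->IBN_c": 14
drives:
  sc:      {lead_ms: 23, end_offset_ms: -4, rate_peak: 1000, rate_end: 700,
            width_ms: 0.6, amplitude: 13, amplitude_ebn: 3}
  fn_contra: {lead_ms: 20, end_offset_ms: -10.5, rate: 200, width_ms: 1.0,
              amplitude: 33, amplitude_ebn: 38}
  fn_ipsi: {onset_offset_ms: -16, duration_ms: 12, rate: 200, width_ms: 1.0,
            amplitude: 85}
  opn_tonic: {amplitude: 12}   # sustained fixation-system excitation of the OPN
  opn_resume: {offset_ms: -4, duration_ms: 25, amplitude: 25}
  ebn_demo: {rate: 800, width_ms: 0.5, amplitude: 50}  # isolated-EBN drive
controller:
  tau_gac_ms: 24.1
  tau_gde_ms: 20.6
  tau_tde_ms: 8.7
  tau_tac_ms: 9.0
  latent_ms: 120
  pulse_N: 0.45          # fiber-saturation innervation during the burst
  fixation_F0_N: 0.297   # common fixation tension at the primary position
  agonist_share: 0.99    # agonist share of the differential fixation tension
  rate_smooth_ms: 6
  burst_rate_hz: 250     # AN rate above this is the saturated burst regime
  pause_rate_hz: 20      # ON rate below this is the saccadic pause
  min_rate_delta_hz: 0.5 # resolution guard for the rate->tension map
plant:
  # whole-muscle values; element values derive via the series/parallel
  # scaling (n columns of m fibers plus two tendons each)
  K_se: 125
  B_2: 0.5
  K_lt: 60.7
  B_1: 1.355
  J_p: 5.0e-4
  B_p: 0.054
  K_p: 39.9
  r_m: 0.01
  "n": 1
  m: 100
  stretch_m: 3.705e-3
  dt_ms: 0.01
  velocity_threshold_deg_s: 20
scenarios:
  latent_ms: 120
  table:
    - {name: 4deg,  magnitude: 4,  burst_ms: 40, n_active: 48,  end_cal_ms: 1.4}
    - {name: 8deg,  magnitude: 8,  burst_ms: 42, n_active: 76,  end_cal_ms: 2.5}
    - {name: 12deg, magnitude: 12, burst_ms: 52, n_active: 75,  end_cal_ms: 1.9}
    - {name: 16deg, magnitude: 16, burst_ms: 56, n_active: 100, end_cal_ms: 2.8}
    - {name: 20deg, magnitude: 20, burst_ms: 65, n_active: 92,  end_cal_ms: 3.1}
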