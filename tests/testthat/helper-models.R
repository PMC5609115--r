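# Shared fixtures, built in code. Heavier simulation products used by
# several tests are cached per session in `.fixtures`.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a minimal passive single-compartment model (1000 um^2 of membrane)
passive_single <- function(gleak = 2e-4, E_leak = -65, L = 100,
                           d = 1000 / (100 * pi)) {
  morph <- morphology(data.frame(id = 1L, parent = NA, length = L, diam = d,
                                 region = "soma"))
  mech <- mechanism_set(
    channels = list(channel_spec("leak", "nonspecific", gleak,
                                 driving = "fixed", E_fix = E_leak)),
    na_pump = pump_spec(0, 0, 0, 0, density = 0),
    ca_pump = pump_spec(0, 0, 0, 0, density = 0),
    ncx = ncx_spec(I_max = 0), buffer = NULL,
    V_init = E_leak)
  neuron_model(morph, mech)
}

# unbranched passive cable of n segments
passive_cable <- function(n = 50, L = 20, d = 2, gleak = 2e-4,
                          E_leak = -65, Ra = 150) {
  morph <- morphology(data.frame(id = seq_len(n),
                                 parent = c(NA, seq_len(n - 1)),
                                 length = L, diam = d, region = "soma"))
  mech <- mechanism_set(
    channels = list(channel_spec("leak", "nonspecific", gleak,
                                 driving = "fixed", E_fix = E_leak)),
    na_pump = pump_spec(0, 0, 0, 0, density = 0),
    ca_pump = pump_spec(0, 0, 0, 0, density = 0),
    ncx = ncx_spec(I_max = 0), buffer = NULL, Ra = Ra,
    V_init = E_leak)
  neuron_model(morph, mech)
}

# single compartment with the default Na+/K+ pump only (no channels except
# leak), used for the pump mass-balance checks
pump_single <- function(Na_init = 10, density = 1e-11, kinetic = FALSE) {
  morph <- morphology(data.frame(id = 1L, parent = NA, length = 20,
                                 diam = 20, region = "soma"))
  np <- default_na_pump()
  np$density <- density
  mech <- mechanism_set(
    channels = list(channel_spec("leak", "nonspecific", 2e-4,
                                 driving = "fixed", E_fix = -65)),
    na_pump = np,
    ca_pump = pump_spec(0, 0, 0, 0, density = 0),
    ncx = ncx_spec(I_max = 0), buffer = NULL,
    V_init = -65, Na_init = Na_init, na_pump_kinetic = kinetic)
  neuron_model(morph, mech)
}

# ---------------------------------------------------------------------------
# Heavy shared simulation products (built once per test session). Protocol
# durations follow the published protocols; morphologies are the reduced
# archetypes, so these runs finish in seconds each.

fig1_run <- function(kind) {
  fixture(paste0("fig1_", kind), function() {
    hold <- if (kind == "purkinje_like") -0.05 else 0
    exp_spike_train(build_model(kind), frequency = 30, duration = 2,
                    t_post = 4, holding = hold, record_every = 4L)
  })
}

# pyramidal synaptic-train runs at tripled spatial resolution (diffusion
# accuracy), distal site, with plain / spine-corrected / frozen variants
fig2_runs <- function() {
  fixture("fig2", function() {
    m <- build_model("pyramidal_like", spatial_resolution = 3)
    exp_synaptic_train(m)
  })
}

# same protocol at the proximal site (spine-corrected only)
fig3_proximal <- function() {
  fixture("fig3_prox", function() {
    m <- build_model("pyramidal_like", spatial_resolution = 3)
    seg <- m$segments$id[segment_index(m, region = "dendrite_proximal",
                                       which = "mid")]
    m2 <- neuron_model(m$morph, with_spine_correction(m$mech))
    ev <- make_synaptic_train(5, 4, seg, t0 = 100,
                              probe_after = c(2000, 9000))
    list(trace = run_protocol(m2, protocol(t_stop = max(ev$time) + 2000,
                                           events = ev),
                              solver_config(record_every = 8L)),
         events = ev, site = seg)
  })
}

fig5_hot_zone <- function() {
  fixture("fig5_hot", function() {
    exp_ca_tagging(build_model("pyramidal_like", spatial_resolution = 2),
                   site = "hot_zone", coincident = "pulses", g_max = 1)
  })
}

fig5_distal <- function() {
  fixture("fig5_distal", function() {
    exp_ca_tagging(build_model("pyramidal_like", spatial_resolution = 2),
                   site = "distal", coincident = "pulses")
  })
}

fig5_purkinje <- function() {
  fixture("fig5_purkinje", function() {
    exp_ca_tagging(build_model("purkinje_like", spatial_resolution = 2),
                   site = "distal", coincident = "climbing_fiber",
                   duration = 2, holding = -0.05)
  })
}

# distributed input, scaled to the reduced cell (25 + 25 presynaptic
# trains give the ~7 Hz background of the full-size protocol)
fig6_run <- function() {
  fixture("fig6", function() {
    m <- build_model("pyramidal_like", spatial_resolution = 2)
    spec <- distributed_input_spec(
      n_cortical = 25, n_thalamic = 25,
      epochs = data.frame(start = c(4, 12), duration = 2.5))
    exp_distributed_input(m, spec, t_stop = 18000, seed = 7,
                          bin_width = 500)
  })
}
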