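## Named mechanism presets for the reduced archetypes.
##
## The underlying detailed models carry their kinetic constants in code, not
## in print; the values below are this package's own reduced parameter set,
## chosen to reproduce the qualitative regimes (spike initiation at the AIS,
## dendritic Na+ channels only in the mitral-like cell, pump equilibrium at
## 10 mM [Na+]i, stable-state Ca2+ rising with [Na+]i) and freely
## overridable through the `overrides` argument.

## ---------------------------------------------------------------------------
## Channel kinetics (Hodgkin-Huxley style, Boltzmann/bell descriptors)

.chan_na_t <- function(gbar) {
  channel_spec("na_t", "Na", gbar,
               gates = list(
                 gate_spec(3, vh = -33, k = 6, tau_min = 0.04, tau_amp = 0.25,
                           vt = -38, ka = 14, kb = 14),
                 gate_spec(1, vh = -54, k = -7, tau_min = 0.4, tau_amp = 7,
                           vt = -55, ka = 14, kb = 14)),
               driving = "nernst_dynamic")
}

.chan_na_p <- function(gbar) {
  channel_spec("na_p", "Na", gbar,
               gates = list(gate_spec(1, vh = -52, k = 4.6, tau_min = 2)),
               driving = "nernst_dynamic")
}

.chan_kdr <- function(gbar, E_K = -90) {
  channel_spec("kdr", "K", gbar,
               gates = list(gate_spec(4, vh = -37, k = 9, tau_min = 0.35,
                                      tau_amp = 5, vt = -50, ka = 18,
                                      kb = 18)),
               driving = "fixed", E_fix = E_K)
}

.chan_ca_hva <- function(pbar) {
  channel_spec("ca_hva", "Ca", pbar,
               gates = list(gate_spec(2, vh = -22, k = 7, tau_min = 1.5)),
               driving = "ghk")
}

## mid-threshold Ca channel used for the dendritic "hot zone": activates
## already at modest depolarisations, so coincident somatic bursts drive
## regenerative Ca2+ influx at the zone
.chan_ca_mid <- function(pbar) {
  channel_spec("ca_mid", "Ca", pbar,
               gates = list(
                 gate_spec(2, vh = -38, k = 6, tau_min = 2),
                 gate_spec(1, vh = -45, k = -6, tau_min = 25)),
               driving = "ghk")
}

.chan_leak <- function(gbar, E_leak = -70) {
  channel_spec("leak", "nonspecific", gbar, gates = list(),
               driving = "fixed", E_fix = E_leak)
}

## ---------------------------------------------------------------------------
## Pump / exchanger / buffer presets (shared "mitral-fitted" constants)

#' Default Na+/K+ pump kinetics
#'
#' Two-reaction constants placing the pump equilibrium at 10 mM [Na+]i
#' (with 150 mM outside) and the half-saturation of the steady-state
#' current near 40 mM, so the current rises steeply above ~20 mM.
#' Densities in mol/cm^2: soma 1e-11, AIS/axon 5e-12, dendrites 1e-15.
#'
#' @export
default_na_pump <- function() {
  pump_spec(k1 = 1e-5, k2 = 0.593, k3 = 0.02, k4 = 1e-10,
            density = c(soma = 1e-11, AIS = 5e-12, axon_node = 5e-12,
                        axon_myelin = 5e-12, dendrite_proximal = 1e-15,
                        dendrite_distal = 1e-15, tuft = 1e-15),
            stoichiometry = 3, charge_per_cycle = 1)
}

#' Default plasma-membrane Ca2+ pump kinetics
#'
#' Stoichiometry 1, two charges per cycle; equilibrium at 50 nM [Ca2+]i
#' (2 mM outside), half-saturation near 0.8 uM. Dendritic density 2e-14
#' mol/cm^2, six-fold higher in soma and axon.
#'
#' @export
default_ca_pump <- function() {
  pump_spec(k1 = 100, k2 = 0.02, k3 = 0.05, k4 = 6.25e-3,
            density = c(soma = 1.2e-13, AIS = 1.2e-13, axon_node = 1.2e-13,
                        axon_myelin = 1.2e-13, dendrite_proximal = 2e-14,
                        dendrite_distal = 2e-14, tuft = 2e-14),
            stoichiometry = 1, charge_per_cycle = 2)
}

#' Default Na+/Ca2+ exchanger parameters (Courtemanche constants)
#' @param I_max maximal current density (mA/cm^2)
#' @param electrogenic include the exchanger current in the membrane
#'   equation
#' @export
default_ncx <- function(I_max = 0.05, electrogenic = TRUE) {
  ncx_spec(I_max = I_max, gamma = 0.35, km_Na = 87.5, km_Ca = 1.38,
           k_sat = 0.1, electrogenic = electrogenic)
}

#' Default Ca2+ buffer (fast endogenous buffer, capacity ~50 at rest)
#' @export
default_buffer <- function() {
  buffer_spec(total_buffer = 0.1, k_on = 50, k_off = 0.1)
}

## ---------------------------------------------------------------------------
## Archetype mechanism presets

#' Mechanism preset for an archetype
#'
#' `mitral_like` carries active Na+ conductance in its distal dendrites and
#' tuft; `pyramidal_like` and `purkinje_like` dendrites have very low Na+
#' conductance, so their dendritic [Na+]i responds to synaptic input only.
#' The pyramidal preset removes the electrogenic effect of the exchanger
#' (its voltage effect is folded into the original fit) and carries a
#' Ca2+-channel hot zone at the proximal tuft; the Purkinje preset has a
#' myelinated axon (low capacitance, passive) with excitable nodes of
#' Ranvier.
#'
#' @param kind archetype name
#' @param overrides named list replacing individual `mechanism_set` fields
#'   after construction
#' @return a [mechanism_set()]
#' @export
archetype_mechanisms <- function(kind = c("mitral_like", "pyramidal_like",
                                          "purkinje_like"),
                                 overrides = list()) {
  kind <- match.arg(kind)
  E_K <- -90
  gleak <- 2e-4
  chans <- switch(kind,
    mitral_like = list(
      .chan_na_t(c(soma = 0.08, AIS = 0.8, dendrite_proximal = 0.04,
                   dendrite_distal = 0.05, tuft = 0.05)),
      .chan_na_p(c(soma = 2e-5, AIS = 5e-5, dendrite_proximal = 2e-5,
                   dendrite_distal = 3e-5, tuft = 3e-5)),
      .chan_kdr(c(soma = 0.06, AIS = 0.3, dendrite_proximal = 0.02,
                  dendrite_distal = 0.02, tuft = 0.02), E_K),
      .chan_ca_hva(c(tuft = 2e-5, dendrite_distal = 5e-6)),
      .chan_leak(gleak)),
    pyramidal_like = list(
      .chan_na_t(c(soma = 0.15, AIS = 0.9, dendrite_proximal = 1e-3,
                   dendrite_distal = 1e-3, tuft = 1e-3)),
      .chan_na_p(c(soma = 2e-5, AIS = 5e-5)),
      .chan_kdr(c(soma = 0.08, AIS = 0.35, dendrite_proximal = 5e-3,
                  dendrite_distal = 5e-3, tuft = 5e-3), E_K),
      .chan_ca_hva(c(soma = 2e-6, dendrite_distal = 2e-6)),
      .chan_ca_mid(c(tuft = 5e-5)),
      .chan_leak(gleak)),
    purkinje_like = list(
      .chan_na_t(c(soma = 0.12, AIS = 1.0, axon_node = 0.6,
                   dendrite_proximal = 1e-3, dendrite_distal = 1e-3)),
      .chan_na_p(c(soma = 5e-5, AIS = 1e-4)),
      .chan_kdr(c(soma = 0.1, AIS = 0.4, axon_node = 0.25,
                  dendrite_proximal = 5e-3, dendrite_distal = 5e-3), E_K),
      .chan_ca_hva(c(dendrite_proximal = 2e-5, dendrite_distal = 2e-5)),
      .chan_leak(c(soma = gleak, AIS = gleak, axon_node = gleak,
                   axon_myelin = 1e-5, dendrite_proximal = gleak,
                   dendrite_distal = gleak, tuft = gleak))))
  cm <- if (kind == "purkinje_like") {
    c(soma = 1, AIS = 1, axon_node = 1, axon_myelin = 0.05,
      dendrite_proximal = 1, dendrite_distal = 1, tuft = 1)
  } else 1
  ca_pump <- default_ca_pump()
  ncx <- default_ncx(electrogenic = kind != "pyramidal_like")
  if (kind == "purkinje_like") {
    ## same retention logic for the Purkinje dendrites (parallel-fiber
    ## sites): slower Ca2+ turnover, unchanged stable-state curve
    for (tag in c("dendrite_proximal", "dendrite_distal")) {
      ca_pump$density[tag] <- ca_pump$density[[tag]] / 3
    }
    ncx$I_max <- c(soma = 0.05, AIS = 0.05, axon_node = 0.05,
                   axon_myelin = 0.05, dendrite_proximal = 0.05 / 3,
                   dendrite_distal = 0.05 / 3, tuft = 0.05)
  }
  if (kind == "pyramidal_like") {
    ## slow Ca2+ turnover in the apical tuft (hot zone): pump density and
    ## exchanger maximal current scaled down together, which leaves the
    ## stable-state curve untouched but lengthens the local Ca2+
    ## relaxation time, so coincident influx is retained for seconds
    ca_pump$density["tuft"] <- ca_pump$density[["tuft"]] / 4
    ncx$I_max <- c(soma = 0.05, AIS = 0.05, axon_node = 0.05,
                   axon_myelin = 0.05, dendrite_proximal = 0.05,
                   dendrite_distal = 0.05, tuft = 0.0125)
  }
  mech <- mechanism_set(
    channels = chans,
    na_pump = default_na_pump(),
    ca_pump = ca_pump,
    ncx = ncx,
    buffer = default_buffer(),
    diffusion = diffusion_spec(D_Na = 0.3),
    cm = cm, Ra = 150, E_K = E_K)
  mech[names(overrides)] <- overrides
  mech
}

#' Spine-corrected variant of a mechanism set
#'
#' Applies the 10-fold reduction of the dendritic Na+ diffusion coefficient
#' that linearly approximates the hindrance by dendritic spines.
#'
#' @param mech a [mechanism_set()]
#' @export
with_spine_correction <- function(mech) {
  mech$diffusion$spine_correction <- TRUE
  mech
}

#' Distributed-input variant of the Na+/K+ pump
#'
#' Under sustained background synaptic input the standard pump lets
#' [Na+]i creep upward; this transform lowers the pump's [Na+]i
#' equilibrium to a quarter of its value (by scaling the reverse-rate
#' product by 1/64 = (1/4)^3) and raises the dendritic density to
#' 50e-15 mol/cm^2.
#'
#' @param mech a [mechanism_set()]
#' @export
with_distributed_input_pump <- function(mech) {
  p <- mech$na_pump
  p$k2 <- p$k2 / 64
  for (tag in c("dendrite_proximal", "dendrite_distal", "tuft")) {
    p$density[tag] <- 50e-15
  }
  mech$na_pump <- p
  mech
}

#' Purkinje-style exchanger substitution
#'
#' Replaces most of the Ca2+ pumping with Na+/Ca2+ exchange: the exchanger
#' maximal current in each region is set from the local Ca2+-pump density
#' (x 1e8 mA/mol) and the pump density is then reduced 1e5-fold.
#'
#' @param mech a [mechanism_set()]
#' @export
with_ncx_substitution <- function(mech) {
  rho <- mech$ca_pump$density
  mech$ncx$I_max <- rho * 1e8
  mech$ca_pump$density <- rho / 1e5
  mech
}

#' Build a ready-to-run archetype model
#'
#' @param kind archetype name
#' @param spatial_resolution morphology subdivision factor
#' @param mech_overrides passed to [archetype_mechanisms()]
#' @param morph_params passed to [build_archetype()]
#' @param freeze_na fixed-[Na+]i control switch
#' @export
build_model <- function(kind = c("mitral_like", "pyramidal_like",
                                 "purkinje_like"),
                        spatial_resolution = 1L, mech_overrides = list(),
                        morph_params = list(), freeze_na = FALSE) {
  kind <- match.arg(kind)
  neuron_model(build_archetype(kind, params = morph_params,
                               spatial_resolution = spatial_resolution),
               archetype_mechanisms(kind, overrides = mech_overrides),
               freeze_na = freeze_na)
}
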