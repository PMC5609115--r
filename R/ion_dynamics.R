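## Ion dynamics: accumulation, longitudinal diffusion, the kinetic Na+/K+
## pump and its steady-state closed form, Ca2+ buffering/pumping, and the
## Na+/Ca2+ exchanger (Courtemanche formulation).

#' Pump specification (two-reaction kinetic scheme)
#'
#' The pump binds `stoichiometry` intracellular ions in a single lumped
#' reaction (`k1` forward, `k2` reverse) and releases them extracellularly
#' (`k3` forward, `k4` reverse), moving `charge_per_cycle` net elementary
#' charges per cycle (1 for the 3:2 Na+/K+ pump, 2 for the plasma-membrane
#' Ca2+ pump). Rates `k1`, `k4` are in 1/(mM^s ms); `k2`, `k3` in 1/ms.
#' `density` is the pump surface density in mol/cm^2, either a scalar or a
#' named vector over region tags.
#'
#' @param k1,k2,k3,k4 kinetic rate constants (all >= 0)
#' @param density total pump density, mol/cm^2 (scalar or named by region)
#' @param stoichiometry ions moved per cycle
#' @param charge_per_cycle net elementary charges per cycle
#' @export
pump_spec <- function(k1, k2, k3, k4, density, stoichiometry = 3,
                      charge_per_cycle = 1) {
  stopifnot(k1 >= 0, k2 >= 0, k3 >= 0, k4 >= 0, all(density >= 0),
            stoichiometry >= 1, charge_per_cycle >= 1)
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, density = density,
                 stoichiometry = stoichiometry,
                 charge_per_cycle = charge_per_cycle), class = "pump_spec")
}

#' Na+/Ca2+ exchanger specification
#'
#' @param I_max maximal current density (mA/cm^2)
#' @param gamma voltage-dependence (position of the energy barrier), in [0,1]
#' @param km_Na,km_Ca dissociation constants (mM)
#' @param k_sat low-potential saturation factor
#' @param electrogenic whether the exchanger current enters the membrane
#'   equation (its ionic fluxes always enter the concentration balances)
#' @export
ncx_spec <- function(I_max, gamma = 0.35, km_Na = 87.5, km_Ca = 1.38,
                     k_sat = 0.1, electrogenic = TRUE) {
  stopifnot(I_max >= 0, gamma >= 0, gamma <= 1, k_sat >= 0)
  structure(list(I_max = I_max, gamma = gamma, km_Na = km_Na, km_Ca = km_Ca,
                 k_sat = k_sat, electrogenic = electrogenic),
            class = "ncx_spec")
}

#' Ca2+ buffer specification (single kinetic buffer)
#' @param total_buffer total buffer concentration (mM)
#' @param k_on binding rate (1/(mM ms))
#' @param k_off unbinding rate (1/ms)
#' @export
buffer_spec <- function(total_buffer, k_on, k_off) {
  stopifnot(total_buffer >= 0, k_on >= 0, k_off >= 0)
  structure(list(total_buffer = total_buffer, k_on = k_on, k_off = k_off),
            class = "buffer_spec")
}

#' Longitudinal diffusion specification
#'
#' `spine_correction = TRUE` multiplies the *dendritic* diffusion
#' coefficient by 0.1, the linear stand-in for the hindrance of diffusion by
#' dendritic spines. Ca2+ does not diffuse by default.
#'
#' @param D_Na Na+ diffusion coefficient (um^2/ms); 0.3 is the experimental
#'   dendritic value
#' @param spine_correction logical
#' @param Ca_diffusible logical; if TRUE Ca2+ diffuses with `D_Ca`
#' @param D_Ca Ca2+ diffusion coefficient (um^2/ms)
#' @export
diffusion_spec <- function(D_Na = 0.3, spine_correction = FALSE,
                           Ca_diffusible = FALSE, D_Ca = 0.22) {
  stopifnot(D_Na > 0)
  structure(list(D_Na = D_Na, spine_correction = spine_correction,
                 Ca_diffusible = Ca_diffusible, D_Ca = D_Ca),
            class = "diffusion_spec")
}

## effective per-segment Na diffusion coefficient
effective_D_Na <- function(spec, regions) {
  D <- rep(spec$D_Na, length(regions))
  if (isTRUE(spec$spine_correction)) {
    dend <- regions %in% c("dendrite_proximal", "dendrite_distal", "tuft")
    D[dend] <- D[dend] * 0.1
  }
  D
}

#' Concentration change rate from a membrane current
#'
#' Converts a net membrane current (outward positive, nA) into the rate of
#' change of the intracellular concentration of the carrying ion,
#' d[ion]/dt = -I / (z F V). Inward current (negative in this convention)
#' raises the concentration: -1 nA of Na+ current into 1000 um^3 gives
#' +1.0364e-2 mM/ms.
#'
#' @param I_nA net membrane current of the ion (nA, outward positive)
#' @param valence ionic valence
#' @param volume compartment volume (um^3)
#' @return d[ion]i/dt in mM/ms
#' @export
accumulation_rate <- function(I_nA, valence, volume) {
  if (any(volume <= 0)) stop("accumulation_rate: volume must be positive")
  -I_nA * RATE_PER_NA_UM3 / (valence * volume)
}

#' One explicit step of longitudinal diffusion
#'
#' Flux-form (conservative) exchange of ion *amounts* between adjacent
#' segments: J = D * (C_k - C_j) * A_cross / dx, with dx the distance
#' between segment centres and A_cross the smaller of the two cross
#' sections. The scheme conserves the total amount exactly.
#'
#' @param conc per-segment concentration vector (mM), aligned with
#'   `m$segments`
#' @param m a [morphology()]
#' @param spec a [diffusion_spec()]
#' @param dt time step (ms)
#' @param ion `"Na"` or `"Ca"`
#' @return updated concentration vector
#' @export
diffusion_step <- function(conc, m, spec, dt, ion = "Na") {
  stopifnot(dt > 0, length(conc) == n_segments(m))
  s <- m$segments
  geo <- segment_geometry(s$length, s$diam)
  idx <- match(s$parent, s$id)
  D <- if (ion == "Na") effective_D_Na(spec, s$region)
       else rep(spec$D_Ca, nrow(s))
  amount <- conc * geo$volume
  for (i in which(!is.na(idx))) {
    j <- idx[i]
    dx <- (s$length[i] + s$length[j]) / 2
    A <- min(geo$cross_section[i], geo$cross_section[j])
    Dij <- (D[i] + D[j]) / 2
    J <- Dij * (conc[j] - conc[i]) * A / dx      # mM um^3 / ms into i
    amount[i] <- amount[i] + J * dt
    amount[j] <- amount[j] - J * dt
  }
  amount / geo$volume
}

#' Steady-state Na+/K+ pump current
#'
#' Closed form obtained by assuming the loaded pump state is in equilibrium:
#' I = (F q / s) * rho * (k1 k3 Ci^s - k2 k4 Co^s) /
#'     (k1 Ci^s + k4 Co^s + k2 + k3),
#' with s the stoichiometry and q the charge moved per cycle. Outward
#' positive, in mA/cm^2; monotonically non-decreasing in the intracellular
#' concentration. Also used for the Ca2+ pump (s = 1, q = 2).
#'
#' @param Ci intracellular concentration of the pumped ion (mM)
#' @param Co extracellular concentration (mM)
#' @param spec a [pump_spec()]
#' @param density pump density override (mol/cm^2); defaults to
#'   `spec$density` (which must then be a scalar)
#' @return current density (mA/cm^2, outward positive)
#' @export
pump_current_steady_state <- function(Ci, Co, spec, density = NULL) {
  stopifnot(all(Ci >= 0))
  rho <- if (is.null(density)) spec$density else density
  s <- spec$stoichiometry
  num <- spec$k1 * spec$k3 * Ci^s - spec$k2 * spec$k4 * Co^s
  den <- spec$k1 * Ci^s + spec$k4 * Co^s + spec$k2 + spec$k3
  (FARADAY * spec$charge_per_cycle / s) * rho * num / den * MOLFLUX_TO_MA
}

#' Kinetic pump update
#'
#' Integrates the loaded-state occupancy ODE
#' d[pumpNa]/dt = [pump] (k1 Ci^s + k4 Co^s) - [pumpNa] (k2 + k3)
#' exactly over `dt` (it is linear at frozen concentrations) and returns the
#' instantaneous current (F q / s) * s * (k1 [pump] Ci^s - k2 [pumpNa]),
#' i.e. the net charge flux of the binding reaction.
#'
#' @param occupancy loaded-pump surface density (mol/cm^2)
#' @param Ci,Co concentrations (mM)
#' @param spec a [pump_spec()]
#' @param dt time step (ms)
#' @param density pump density override (mol/cm^2)
#' @return list with `current` (mA/cm^2, at the updated occupancy) and
#'   `occupancy` (mol/cm^2)
#' @export
pump_current_kinetic <- function(occupancy, Ci, Co, spec, dt, density = NULL) {
  rho <- if (is.null(density)) spec$density else density
  if (any(occupancy < 0) || any(occupancy > rho + 1e-15 * max(rho, 1))) {
    stop("pump occupancy out of [0, total_density]")
  }
  s <- spec$stoichiometry
  a <- spec$k1 * Ci^s + spec$k4 * Co^s     # loading rate from unloaded state
  b <- spec$k2 + spec$k3                   # unloading rate
  pinf <- ifelse(a + b > 0, rho * a / (a + b), occupancy)
  occ <- pinf + (occupancy - pinf) * exp(-(a + b) * dt)
  occ <- pmin(pmax(occ, 0), rho)
  cur <- (FARADAY * spec$charge_per_cycle / s) *
    (spec$k1 * (rho - occ) * Ci^s - spec$k2 * occ) * MOLFLUX_TO_MA
  list(current = cur, occupancy = occ)
}

#' Na+/Ca2+ exchanger current
#'
#' Courtemanche-type expression. Positive (outward) current corresponds to
#' the reverse mode: 3 Na+ out, 1 Ca2+ in, so a positive current *raises*
#' intracellular Ca2+ at a molar rate I/F and lowers Na+ at 3 I/F. The
#' current reverses at V = 3 E_Na - 2 E_Ca.
#'
#' @param Na_i,Na_o,Ca_i,Ca_o concentrations (mM), all positive
#' @param V membrane potential (mV)
#' @param spec an [ncx_spec()]
#' @param T_K temperature (K)
#' @return current density (mA/cm^2, outward positive)
#' @export
ncx_current <- function(Na_i, Na_o, Ca_i, Ca_o, V, spec, T_K = BODY_TEMP_K) {
  if (any(c(Na_i, Na_o, Ca_i, Ca_o) <= 0)) {
    stop("ncx_current: concentrations must be positive")
  }
  th <- V / rtf_mV(T_K)
  e1 <- exp(spec$gamma * th)
  e2 <- exp((spec$gamma - 1) * th)
  num <- Na_i^3 * Ca_o * e1 - Na_o^3 * Ca_i * e2
  den <- (spec$km_Na^3 + Na_o^3) * (spec$km_Ca + Ca_o) * (1 + spec$k_sat * e2)
  spec$I_max * num / den
}

#' NCX reversal potential
#'
#' @inheritParams ncx_current
#' @return 3 E_Na - 2 E_Ca in mV
#' @export
ncx_reversal <- function(Na_i, Na_o, Ca_i, Ca_o, T_K = BODY_TEMP_K) {
  3 * nernst(Na_i, Na_o, 1, T_K) - 2 * nernst(Ca_i, Ca_o, 2, T_K)
}

#' Total rate of intracellular Ca2+ change
#'
#' Sums the exchanger flux (+I_NCX / F, molar, per the charge-per-cycle of
#' one), the Ca2+ pump extrusion (one ion per cycle, I_pump / (2F)), the
#' kinetic buffering flux and an optional voltage-gated Ca2+ influx term.
#' Surface fluxes are converted to concentration rates with the segment's
#' area-to-volume ratio.
#'
#' @param Ca_i,Na_i intracellular concentrations (mM)
#' @param bound_buffer bound-buffer concentration (mM)
#' @param V membrane potential (mV)
#' @param ncx an [ncx_spec()]
#' @param ca_pump a [pump_spec()] (stoichiometry 1, charge 2)
#' @param buffer a [buffer_spec()] (or NULL for no buffer)
#' @param area,volume segment membrane area (um^2) and volume (um^3)
#' @param I_ca_channel voltage-gated Ca2+ channel current density
#'   (mA/cm^2, outward positive; inward influx is negative)
#' @param Na_o,Ca_o external concentrations (mM)
#' @param T_K temperature (K)
#' @param ca_pump_density optional density override (mol/cm^2)
#' @return d[Ca2+]i/dt in mM/ms
#' @export
ca_balance_rate <- function(Ca_i, Na_i, bound_buffer, V, ncx, ca_pump, buffer,
                            area, volume, I_ca_channel = 0,
                            Na_o = 150, Ca_o = 2, T_K = BODY_TEMP_K,
                            ca_pump_density = NULL) {
  I_ncx <- ncx_current(Na_i, Na_o, Ca_i, Ca_o, V, ncx, T_K)
  I_pmp <- pump_current_steady_state(Ca_i, Ca_o, ca_pump,
                                     density = ca_pump_density)
  ## surface molar fluxes -> mM/ms: I(mA/cm^2) * A(um^2) * 0.01 = nA;
  ## nA -> mM/ms via RATE_PER_NA_UM3/(z_eff * vol) with z_eff the charges
  ## moved per transported Ca2+ (1 for NCX, 2 for the pump, 2 for channels)
  to_rate <- function(I, z_eff) I * DENSITY_TO_NA * area * RATE_PER_NA_UM3 /
    (z_eff * volume)
  r <- to_rate(I_ncx, 1) - to_rate(I_pmp, 2) - to_rate(I_ca_channel, 2)
  if (!is.null(buffer)) {
    free <- buffer$total_buffer - bound_buffer
    r <- r - (buffer$k_on * Ca_i * free - buffer$k_off * bound_buffer)
  }
  r
}
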