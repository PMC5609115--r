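## Voltage-gated conductances with dynamic driving forces.

#' Nernst equilibrium potential
#'
#' @param Ci intracellular concentration (mM)
#' @param Co extracellular concentration (mM)
#' @param z ionic valence (non-zero integer)
#' @param T_K temperature in kelvin (default physiological, 310.15 K)
#' @return equilibrium potential in mV
#' @examples
#' nernst(15, 150, 1)       # E_Na at moderately elevated [Na+]i, ~ +61.5 mV
#' nernst(1e-4, 2, 2)       # E_Ca at rest
#' @export
nernst <- function(Ci, Co, z, T_K = BODY_TEMP_K) {
  if (any(Ci <= 0) || any(Co <= 0)) {
    stop("nernst: concentrations must be positive")
  }
  stopifnot(all(z != 0), all(T_K > 0))
  (rtf_mV(T_K) / z) * log(Co / Ci)
}

#' Goldman-Hodgkin-Katz flux current
#'
#' Constant-field current density carried by an ion with permeability `P`.
#' At V -> 0 the expression reduces to `P * z * F * (Ci - Co)` (in
#' consistent units); the implementation switches to a series expansion near
#' V = 0 to avoid 0/0.
#'
#' @param V membrane potential (mV)
#' @param Ci,Co intra-/extracellular concentrations (mM)
#' @param z valence
#' @param P permeability (cm/s)
#' @param T_K temperature (K)
#' @return current density in mA/cm^2 (outward positive)
#' @export
ghk_current <- function(V, Ci, Co, z = 2, P = 1, T_K = BODY_TEMP_K) {
  if (any(Ci < 0) || any(Co < 0) || all(Ci == 0) && all(Co == 0)) {
    stop("ghk_current: need non-negative concentrations, not both zero")
  }
  ## concentrations mM -> mol/cm^3: 1 mM = 1e-6 mol/cm^3
  ci <- Ci * 1e-6; co <- Co * 1e-6
  xi <- z * V / rtf_mV(T_K)          # dimensionless zVF/RT
  ## I (A/cm^2) = P z F xi (ci - co e^-xi) / (1 - e^-xi); -> mA/cm^2
  small <- abs(xi) < 1e-6
  frac <- ifelse(small,
                 ci - co + (ci + co) * xi / 2,        # first-order expansion
                 xi * (ci - co * exp(-xi)) / (1 - exp(-xi)))
  1e3 * P * z * FARADAY * frac
}

## ---------------------------------------------------------------------------
## Gating descriptors. A gate is described by a Boltzmann steady state
##   xinf(V) = 1 / (1 + exp(-(V - vh)/k))      (k < 0 for inactivation)
## and a time constant that is either constant or a skewed bell
##   tau(V) = tau_min + tau_amp / (exp((V - vt)/ka) + exp(-(V - vt)/kb)).
## All parameters are plain numbers carried in the channel spec, so ported
## parameter sets can be loaded from configuration without code changes.

#' Gate descriptor
#' @param exponent integer power of the gate in the open probability
#' @param vh,k Boltzmann half-activation (mV) and slope (mV; negative for
#'   inactivation gates)
#' @param tau_min,tau_amp,vt,ka,kb time-constant parameters (ms, mV); with
#'   `tau_amp = 0` the time constant is the constant `tau_min`
#' @export
gate_spec <- function(exponent, vh, k, tau_min, tau_amp = 0,
                      vt = vh, ka = 20, kb = 20) {
  stopifnot(exponent >= 0, tau_min > 0 || tau_amp > 0)
  list(exponent = exponent, vh = vh, k = k, tau_min = tau_min,
       tau_amp = tau_amp, vt = vt, ka = ka, kb = kb)
}

#' Gate steady state and time constant
#' @param g a [gate_spec()]
#' @param V membrane potential (mV)
#' @export
gate_inf <- function(g, V) 1 / (1 + exp(-(V - g$vh) / g$k))

#' @rdname gate_inf
#' @export
gate_tau <- function(g, V) {
  g$tau_min + if (g$tau_amp > 0)
    g$tau_amp / (exp((V - g$vt) / g$ka) + exp(-(V - g$vt) / g$kb)) else 0
}

#' Channel specification
#'
#' @param name channel name
#' @param ion one of `"Na"`, `"K"`, `"Ca"`, `"nonspecific"`
#' @param gbar named numeric: conductance density (S/cm^2) -- or permeability
#'   (cm/s) for GHK channels -- per region tag; unnamed scalar applies
#'   everywhere
#' @param gates list of [gate_spec()]s
#' @param driving one of `"nernst_dynamic"` (reversal recomputed each step
#'   from current concentrations), `"fixed"` (constant `E_fix`), `"ghk"`
#'   (constant-field flux; required for Ca channels)
#' @param E_fix fixed reversal potential (mV) for `driving = "fixed"`
#' @export
channel_spec <- function(name, ion = c("Na", "K", "Ca", "nonspecific"),
                         gbar, gates = list(),
                         driving = c("nernst_dynamic", "fixed", "ghk"),
                         E_fix = NA_real_) {
  ion <- match.arg(ion); driving <- match.arg(driving)
  stopifnot(all(gbar >= 0))
  if (ion == "Ca" && driving != "ghk") {
    stop("Ca channels must use the GHK driving-force mode")
  }
  if (driving == "fixed" && !is.finite(E_fix)) stop("E_fix required")
  structure(list(name = name, ion = ion, gbar = gbar, gates = gates,
                 driving = driving, E_fix = E_fix), class = "channel_spec")
}

## gbar for a vector of region tags
gbar_for_regions <- function(spec, regions) {
  g <- spec$gbar
  if (is.null(names(g))) return(rep(g[1], length(regions)))
  out <- unname(g[regions])
  out[is.na(out)] <- 0
  out
}

#' Membrane current of one channel
#'
#' For conductance channels returns `gbar * prod(gates^p) * (V - E)` with E
#' either fixed or the Nernst potential recomputed from the supplied
#' concentrations; for GHK channels returns the constant-field flux scaled
#' by the open probability.
#'
#' @param spec a [channel_spec()]
#' @param gate_values numeric vector of current gate values (same order as
#'   `spec$gates`)
#' @param V membrane potential (mV)
#' @param conc named list with entries `Na_i`, `Na_o`, `Ca_i`, `Ca_o` (mM)
#' @param region region tag of the segment (selects the density)
#' @param T_K temperature (K)
#' @return current density, mA/cm^2, outward positive
#' @export
channel_current <- function(spec, gate_values, V, conc, region = "soma",
                            T_K = BODY_TEMP_K) {
  stopifnot(length(gate_values) == length(spec$gates))
  if (any(gate_values < 0 | gate_values > 1)) stop("gate values must be in [0,1]")
  open <- 1
  for (i in seq_along(spec$gates)) {
    open <- open * gate_values[i]^spec$gates[[i]]$exponent
  }
  g <- gbar_for_regions(spec, region)
  if (spec$driving == "ghk") {
    z <- if (spec$ion == "Ca") 2 else 1
    Ci <- if (spec$ion == "Ca") conc$Ca_i else conc$Na_i
    Co <- if (spec$ion == "Ca") conc$Ca_o else conc$Na_o
    return(open * ghk_current(V, Ci, Co, z = z, P = g, T_K = T_K))
  }
  E <- if (spec$driving == "fixed") spec$E_fix
       else switch(spec$ion,
                   Na = nernst(conc$Na_i, conc$Na_o, 1, T_K),
                   Ca = stop("Ca channels must use ghk"),
                   K = spec$E_fix,  # [K+] held fixed; E_K supplied as E_fix
                   nonspecific = spec$E_fix)
  g * open * (V - E)
}

#' Advance gating variables by the exact exponential update
#'
#' Each gate obeys dx/dt = (xinf(V) - x)/tau(V); at frozen V the exact
#' solution over `dt` is `xinf + (x - xinf) * exp(-dt/tau)`, which keeps the
#' gate in [0,1] for any `dt`.
#'
#' @param gate_values numeric vector of gate values
#' @param gates list of [gate_spec()]s
#' @param V membrane potential (mV)
#' @param dt time step (ms)
#' @export
update_gates <- function(gate_values, gates, V, dt) {
  stopifnot(dt > 0, length(gate_values) == length(gates))
  vapply(seq_along(gates), function(i) {
    xi <- gate_inf(gates[[i]], V)
    xi + (gate_values[i] - xi) * exp(-dt / gate_tau(gates[[i]], V))
  }, numeric(1))
}
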