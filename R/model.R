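## Assembly of a runnable cell model: morphology + mechanism set, flattened
## into the per-segment arrays consumed by the C++ stepping core.

#' Mechanism set
#'
#' Bundles everything electrical and chemical about the membrane: channels,
#' pumps, exchanger, buffer, diffusion, passive properties and the external
#' milieu. Densities given as named vectors are resolved per region tag;
#' unnamed scalars apply everywhere.
#'
#' @param channels list of [channel_spec()]
#' @param na_pump,ca_pump [pump_spec()]s (densities in mol/cm^2, named by
#'   region or scalar)
#' @param ncx an [ncx_spec()]; `I_max` may be a named-by-region vector
#' @param buffer a [buffer_spec()] or NULL
#' @param diffusion a [diffusion_spec()]
#' @param cm specific capacitance, uF/cm^2 (scalar or named by region)
#' @param Ra axial resistivity, ohm cm
#' @param E_K fixed K+ reversal potential (mV); [K+] is not a state variable
#' @param Na_o,Ca_o external concentrations (mM)
#' @param T_K temperature (K)
#' @param V_init,Na_init,Ca_init initial state (mV, mM)
#' @param na_pump_kinetic use the explicit occupancy ODE instead of the
#'   steady-state closed form
#' @export
mechanism_set <- function(channels, na_pump, ca_pump, ncx, buffer = NULL,
                          diffusion = diffusion_spec(), cm = 1, Ra = 150,
                          E_K = -90, Na_o = 150, Ca_o = 2, T_K = BODY_TEMP_K,
                          V_init = -65, Na_init = 10, Ca_init = 5e-5,
                          na_pump_kinetic = FALSE) {
  structure(list(channels = channels, na_pump = na_pump, ca_pump = ca_pump,
                 ncx = ncx, buffer = buffer, diffusion = diffusion, cm = cm,
                 Ra = Ra, E_K = E_K, Na_o = Na_o, Ca_o = Ca_o, T_K = T_K,
                 V_init = V_init, Na_init = Na_init, Ca_init = Ca_init,
                 na_pump_kinetic = na_pump_kinetic),
            class = "mechanism_set")
}

## resolve a scalar-or-named-by-region parameter to a per-segment vector
resolve_by_region <- function(x, regions) {
  if (is.null(names(x))) return(rep(unname(x)[1], length(regions)))
  out <- unname(x[regions])
  out[is.na(out)] <- 0
  out
}

#' Runnable neuron model
#'
#' Combines a morphology and a mechanism set, reorders segments so parents
#' precede children (required by the Hines solve) and precomputes geometry
#' and axial conductances.
#'
#' @param morph a [morphology()]
#' @param mech a [mechanism_set()]
#' @param freeze_na freeze [Na+]i at its initial value (the conventional
#'   fixed-concentration control); pump and exchanger currents then stay at
#'   their baseline values and E_Na is constant
#' @export
neuron_model <- function(morph, mech, freeze_na = FALSE) {
  stopifnot(inherits(morph, "morphology"), inherits(mech, "mechanism_set"))
  ord <- tree_order(morph)
  s <- morph$segments[ord, , drop = FALSE]
  geo <- segment_geometry(s$length, s$diam)
  pidx <- match(s$parent, s$id) - 1L  # 0-based, NA for root
  pidx[is.na(pidx)] <- -1L
  ## axial conductance between the centres of segment i and its parent
  g_ax <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    p <- pidx[i] + 1L
    if (p == 0L) next
    R_MOhm <- 0.01 * mech$Ra *
      ((s$length[i] / 2) / geo$cross_section[i] +
       (s$length[p] / 2) / geo$cross_section[p])
    g_ax[i] <- 1 / R_MOhm  # uS
  }
  structure(list(morph = morph, mech = mech, segments = s, parent0 = pidx,
                 geometry = geo, g_axial = g_ax, freeze_na = freeze_na),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat("<neuron_model> ", nrow(x$segments), " segments, ",
      length(x$mech$channels), " channel types",
      if (x$freeze_na) ", [Na+]i FROZEN" else "", "\n", sep = "")
  invisible(x)
}

.ion_code <- c(Na = 0L, K = 1L, Ca = 2L, nonspecific = 3L)
.driving_code <- c(nernst_dynamic = 0L, fixed = 1L, ghk = 2L)

## flatten the model into the list the C++ core expects
compile_model <- function(model, state = NULL) {
  s <- model$segments
  mech <- model$mech
  regions <- s$region
  n <- nrow(s)
  chans <- lapply(mech$channels, function(ch) {
    E_fix <- if (ch$ion == "K" && ch$driving == "nernst_dynamic") mech$E_K
             else ch$E_fix
    gates <- if (length(ch$gates))
      t(vapply(ch$gates, function(g)
        c(g$exponent, g$vh, g$k, g$tau_min, g$tau_amp, g$vt, g$ka, g$kb),
        numeric(8)))
    else matrix(0, 0, 8)
    list(ion = .ion_code[[ch$ion]],
         driving = .driving_code[[ch$driving]],
         E_fix = if (is.finite(E_fix)) E_fix else 0,
         gbar = gbar_for_regions(ch, regions),
         gates = gates)
  })
  st <- function(val, default) {
    v <- if (!is.null(val)) val else default
    if (length(v) == 1L) rep(v, n) else v
  }
  list(parent = model$parent0,
       area = model$geometry$lateral_area,
       volume = model$geometry$volume,
       length = s$length,
       cross_section = model$geometry$cross_section,
       g_axial = model$g_axial,
       cm = resolve_by_region(mech$cm, regions),
       T_K = mech$T_K, Na_o = mech$Na_o, Ca_o = mech$Ca_o, E_K = mech$E_K,
       channels = chans,
       na_pump = list(k1 = mech$na_pump$k1, k2 = mech$na_pump$k2,
                      k3 = mech$na_pump$k3, k4 = mech$na_pump$k4,
                      density = resolve_by_region(mech$na_pump$density, regions),
                      kinetic = as.integer(isTRUE(mech$na_pump_kinetic))),
       ca_pump = list(k1 = mech$ca_pump$k1, k2 = mech$ca_pump$k2,
                      k3 = mech$ca_pump$k3, k4 = mech$ca_pump$k4,
                      density = resolve_by_region(mech$ca_pump$density, regions)),
       ncx = list(I_max = resolve_by_region(mech$ncx$I_max, regions),
                  gamma = mech$ncx$gamma, km_Na = mech$ncx$km_Na,
                  km_Ca = mech$ncx$km_Ca, k_sat = mech$ncx$k_sat,
                  electrogenic = as.integer(isTRUE(mech$ncx$electrogenic))),
       buffer = if (is.null(mech$buffer))
         list(total_buffer = 0, k_on = 0, k_off = 0)
       else list(total_buffer = mech$buffer$total_buffer,
                 k_on = mech$buffer$k_on, k_off = mech$buffer$k_off),
       D_Na = effective_D_Na(mech$diffusion, regions),
       Ca_diffusible = as.integer(isTRUE(mech$diffusion$Ca_diffusible)),
       D_Ca = mech$diffusion$D_Ca,
       V0 = st(state$V, mech$V_init),
       Na0 = st(state$Na, mech$Na_init),
       Ca0 = st(state$Ca, mech$Ca_init),
       freeze_na = as.integer(isTRUE(model$freeze_na)))
}

#' Look up a segment's row index (in solver order) by id or region
#'
#' @param model a [neuron_model()]
#' @param id segment id
#' @param region region tag; `which` selects among multiple matches
#' @param which `"first"`, `"last"` or `"mid"`
#' @export
segment_index <- function(model, id = NULL, region = NULL, which = "first") {
  s <- model$segments
  if (!is.null(id)) {
    i <- match(id, s$id)
    if (is.na(i)) stop("no segment with id ", id)
    return(i)
  }
  hits <- which(s$region == region)
  if (!length(hits)) stop("no segment tagged '", region, "'")
  switch(which, first = hits[1], last = hits[length(hits)],
         mid = hits[ceiling(length(hits) / 2)])
}
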