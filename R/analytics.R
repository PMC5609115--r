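## Derived quantities: spike metrics, sodium entry ratio, effective
## capacitance, the E_Na / pump-current curves, stable-state [Ca2+]i and
## firing-rate summaries.

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings with a refractory period.
#'
#' @param t time vector (ms)
#' @param V voltage vector (mV)
#' @param threshold detection threshold (mV)
#' @param refractory minimum inter-spike interval (ms)
#' @return indices into `t` of the crossings
#' @export
detect_spikes <- function(t, V, threshold = 0, refractory = 1) {
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold) + 1L
  if (!length(up)) return(integer(0))
  keep <- up[1]
  for (i in up[-1]) if (t[i] - t[keep[length(keep)]] >= refractory) {
    keep <- c(keep, i)
  }
  keep
}

#' Per-spike metrics from a voltage trace
#'
#' Peak times, baseline-to-peak amplitudes (baseline = the resting
#' potential at the start of the trace) and, when the trace carries the
#' cumulative global Na+ current, the Na+ charge entering per spike.
#'
#' @param trace a `sim_trace`
#' @param seg segment id for the voltage (default: soma)
#' @param threshold spike threshold (mV)
#' @param window_tail ms appended to each spike window after the downward
#'   threshold crossing (the Na+ tail current integration window)
#' @return data.frame with `peak_time` (ms), `amplitude` (mV) and
#'   `na_entry` (nC, NA when unavailable)
#' @export
spike_metrics <- function(trace, seg = NULL, threshold = -10,
                          window_tail = 2) {
  v <- if (is.null(seg)) trace_at(trace, "V", region = "soma")
       else trace_at(trace, "V", seg = seg)
  idx <- detect_spikes(v$t, v$value, threshold = threshold)
  if (!length(idx)) stop("no spike detected in trace")
  baseline <- v$value[1]
  out <- lapply(idx, function(i) {
    j <- i
    while (j < length(v$t) && v$value[j] >= threshold) j <- j + 1L
    j_tail <- which(v$t <= v$t[j] + window_tail)
    j_tail <- j_tail[length(j_tail)]
    win <- i:j_tail
    pk <- win[which.max(v$value[win])]
    na_entry <- if (!is.null(trace$cum_I_Na)) {
      ## nA ms -> nC; influx is negative (outward-positive convention)
      1e-3 * abs(trace$cum_I_Na[j_tail] - trace$cum_I_Na[max(i - 1L, 1L)])
    } else NA_real_
    data.frame(peak_time = v$t[pk], amplitude = v$value[pk] - baseline,
               na_entry = na_entry)
  })
  do.call(rbind, out)
}

#' Effective membrane capacitance by the two-potential clamp transient
#'
#' Clamps the soma to `V1` until steady state, steps to `V2`, and divides
#' the integrated clamp-current transient (after subtracting the new
#' steady-state current) by the voltage step. For `purkinje_like`-style
#' cells call this on a model whose dendrites were dropped with
#' [remove_region()] first: the dendritic load otherwise inflates the
#' apparent capacitance.
#'
#' @param model a [neuron_model()]
#' @param V1,V2 holding potentials (mV)
#' @param t_settle time at each holding level (ms)
#' @param dt integration step (ms)
#' @return capacitance in nF
#' @export
effective_capacitance <- function(model, V1 = -70, V2 = -60, t_settle = 50,
                                  dt = 0.01) {
  stopifnot(V1 != V2)
  soma_id <- model$segments$id[segment_index(model, region = "soma")]
  cl <- data.frame(t = c(0, t_settle), V = c(V1, V2))
  tr <- run_protocol(model,
                     protocol(t_stop = 2 * t_settle, clamp = cl,
                              clamp_seg = soma_id),
                     solver_config(dt = dt, record_every = 1L),
                     state = list(V = V1))
  if (!all(is.finite(tr$I_clamp))) stop("clamp did not converge")
  i_ss <- tr$I_clamp[length(tr$I_clamp)]
  sel <- tr$t > t_settle
  ## rectangle rule matches the backward-Euler impulse exactly
  Q <- sum((tr$I_clamp[sel] - i_ss)) * dt      # nA ms = pC
  Q / (V2 - V1)                                # pC/mV = nF
}

#' Sodium entry ratio
#'
#' Ratio of the integrated global Na+ charge entering during an action
#' potential to the minimal charge needed to account for the spike
#' amplitude (amplitude x capacitance). 1 is the theoretical optimum; real
#' neurons overlap Na+ and K+ currents and exceed it.
#'
#' @param trace a `sim_trace` recorded with `record_every = 1` (so the
#'   cumulative Na+ current resolves the spike)
#' @param capacitance effective capacitance (nF), from
#'   [effective_capacitance()]
#' @param seg spike-detection segment id (default soma)
#' @param threshold,window_tail spike-window parameters (see
#'   [spike_metrics()])
#' @return one SER value per detected spike
#' @export
sodium_entry_ratio <- function(trace, capacitance, seg = NULL,
                               threshold = -10, window_tail = 2) {
  sm <- spike_metrics(trace, seg = seg, threshold = threshold,
                      window_tail = window_tail)
  ## nC / (mV * nF) : nF mV = pC, nC = 1000 pC
  1000 * sm$na_entry / (sm$amplitude * capacitance)
}

#' Stable-state intracellular calcium for a fixed sodium level
#'
#' Solves the calcium balance with closed voltage-gated channels: exchanger
#' influx (I_max/F prefactor) equals pump extrusion. Because the exchanger
#' numerator is linear in [Ca2+]i and the pump is a linear-over-linear
#' rational function, the root is the positive solution of a quadratic;
#' `method = "root"` instead brackets the same balance with
#' [stats::uniroot()] on [1e-9, Ca_o] as an independent check.
#'
#' @param Na_i fixed intracellular sodium (mM); vectorised
#' @param V membrane potential (mV)
#' @param ncx an [ncx_spec()]
#' @param ca_pump a [pump_spec()] with scalar density
#' @param Na_o,Ca_o external concentrations (mM)
#' @param T_K temperature (K)
#' @param method `"closed_form"` or `"root"`
#' @return stable-state [Ca2+]i in mM
#' @export
stable_state_ca <- function(Na_i, V = -65, ncx, ca_pump, Na_o = 150,
                            Ca_o = 2, T_K = BODY_TEMP_K,
                            method = c("closed_form", "root")) {
  method <- match.arg(method)
  stopifnot(length(ca_pump$density) == 1L)
  one <- function(nai) {
    th <- V / rtf_mV(T_K)
    e1 <- exp(ncx$gamma * th)
    e2 <- exp((ncx$gamma - 1) * th)
    den_ncx <- (ncx$km_Na^3 + Na_o^3) * (ncx$km_Ca + Ca_o) *
      (1 + ncx$k_sat * e2)
    ## molar exchanger rate (mol cm^-2 ms^-1): (I_max/F) * (a1 - a2 Ca)
    sc <- ncx$I_max * 1e-3 / FARADAY / den_ncx  # 1e-3: mA -> A(=C/s), per ms below
    a1 <- sc * nai^3 * Ca_o * e1 * 1e-3
    a2 <- sc * Na_o^3 * e2 * 1e-3
    rho <- ca_pump$density
    k1 <- ca_pump$k1; k2 <- ca_pump$k2; k3 <- ca_pump$k3; k4 <- ca_pump$k4
    K0 <- k4 * Ca_o + k2 + k3
    balance <- function(ca) {
      (a1 - a2 * ca) - rho * (k1 * k3 * ca - k2 * k4 * Ca_o) / (k1 * ca + K0)
    }
    if (method == "root") {
      lo <- 1e-9; hi <- Ca_o
      if (balance(lo) < 0 || balance(hi) > 0) {
        stop("no positive stable-state root in [", lo, ", ", hi, "] mM")
      }
      return(stats::uniroot(balance, c(lo, hi), tol = 1e-15)$root)
    }
    ## (a1 - a2 C)(k1 C + K0) = rho (k1 k3 C - k2 k4 Ca_o)
    A <- -a2 * k1
    B <- a1 * k1 - a2 * K0 - rho * k1 * k3
    Cc <- a1 * K0 + rho * k2 * k4 * Ca_o
    roots <- if (abs(A) < 1e-300) {
      ## exchanger absent: the balance is linear (pump-only equilibrium)
      -Cc / B
    } else {
      disc <- B^2 - 4 * A * Cc
      if (disc < 0) stop("no real stable-state root")
      c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
    }
    pos <- roots[roots > 0 & roots <= Ca_o]
    if (!length(pos)) stop("no positive stable-state root in [0, Ca_o]")
    min(pos)
  }
  vapply(Na_i, one, numeric(1))
}

#' Normalised event-amplitude series
#'
#' For spikes: baseline-to-peak amplitudes normalised to the first spike.
#' For EPSPs: peak minus the pre-event baseline (mean V over the 5 ms
#' preceding each event), normalised to the first event.
#'
#' @param trace a `sim_trace`
#' @param kind `"spike"` or `"epsp"`
#' @param event_times for `"epsp"`: the synaptic event times (ms)
#' @param seg segment id of the recorded voltage (default soma)
#' @param baseline_window ms of pre-event voltage averaged as the EPSP
#'   baseline
#' @param search_window ms after each event searched for the EPSP peak
#' @return numeric vector of normalised amplitudes (first element 1)
#' @export
amplitude_series <- function(trace, kind = c("spike", "epsp"),
                             event_times = NULL, seg = NULL,
                             baseline_window = 5, search_window = 30) {
  kind <- match.arg(kind)
  if (kind == "spike") {
    amps <- spike_metrics(trace, seg = seg)$amplitude
    return(amps / amps[1])
  }
  if (is.null(event_times) || !length(event_times)) {
    stop("epsp amplitude series needs event_times")
  }
  v <- if (is.null(seg)) trace_at(trace, "V", region = "soma")
       else trace_at(trace, "V", seg = seg)
  amps <- vapply(event_times, function(t0) {
    base <- mean(v$value[v$t >= t0 - baseline_window & v$t < t0])
    pk <- max(v$value[v$t >= t0 & v$t <= t0 + search_window])
    pk - base
  }, numeric(1))
  amps / amps[1]
}

#' Averaged firing-rate histogram
#'
#' @param spike_times vector (one run) or list of vectors (multiple runs)
#'   of spike times (ms)
#' @param bin_width bin width (ms)
#' @param t_stop histogram span (ms)
#' @return data.frame with bin `start` (ms) and `rate` (Hz), averaged over
#'   runs
#' @export
rate_histogram <- function(spike_times, bin_width, t_stop) {
  stopifnot(bin_width > 0)
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  breaks <- seq(0, t_stop, by = bin_width)
  if (breaks[length(breaks)] < t_stop) breaks <- c(breaks, t_stop)
  counts <- Reduce(`+`, lapply(spike_times, function(st) {
    graphics::hist(st[st >= 0 & st <= t_stop], breaks = breaks,
                   plot = FALSE)$counts
  }))
  data.frame(start = breaks[-length(breaks)],
             rate = 1000 * counts / diff(breaks) / length(spike_times))
}

#' E_Na as a function of intracellular sodium
#'
#' @param Na_i grid of intracellular sodium values (mM)
#' @param Na_o external sodium (mM)
#' @param T_K temperature (K)
#' @return data.frame with `Na_i` and `E_Na` (mV)
#' @export
ena_curve <- function(Na_i = seq(5, 60, by = 1), Na_o = 150,
                      T_K = BODY_TEMP_K) {
  data.frame(Na_i = Na_i, E_Na = nernst(Na_i, Na_o, 1, T_K))
}

#' Specific Na+/K+ pump current as a function of intracellular sodium
#'
#' @param Na_i grid (mM)
#' @param spec a [pump_spec()]
#' @param density pump density (mol/cm^2)
#' @param Na_o external sodium (mM)
#' @return data.frame with `Na_i` and `I_pump` (mA/cm^2)
#' @export
pump_curve <- function(Na_i = seq(0, 60, by = 1), spec, density,
                       Na_o = 150) {
  data.frame(Na_i = Na_i,
             I_pump = pump_current_steady_state(Na_i, Na_o, spec,
                                                density = density))
}

#' Published full-model benchmark values
#'
#' Absolute benchmark numbers reported for the three detailed source models
#' (sodium entry ratios, end-of-train EPSP reduction, peak AIS pump
#' current). They depend on the full channel complements and reconstructed
#' morphologies whose parameter sets are hosted on ModelDB (entries 185332
#' and 230326) and are not shipped with this package; the reduced
#' archetypes here target the qualitative orderings, not these values.
#'
#' @return data.frame with the quantity, its published value and the flag
#'   that reproducing it requires the ported parameter sets
#' @export
reference_benchmarks <- function() {
  data.frame(
    quantity = c("SER_pyramidal", "SER_mitral", "SER_purkinje",
                 "EPSP_reduction_percent", "peak_pump_current_pA"),
    value = c(1.76, 3.6, 5.6, 17, 400),
    requires_ported_parameters = TRUE,
    source = "ModelDB 185332 / 230326 (not bundled)")
}
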