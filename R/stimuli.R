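## Stimulus generation: current-pulse trains, deterministic synaptic trains,
## climbing-fiber volleys and the stochastic distributed ("cortical" /
## "thalamic") input. This is the package's synthetic-input generator; all
## schedules are deterministic functions of (spec, morphology, seed).

#' Double-exponential synaptic conductance waveform
#'
#' g(t) = g_max * N * (exp(-t/tau_off) - exp(-t/tau_on)) for t >= 0 and 0
#' before the event; N normalises the peak to exactly `g_max` (peak
#' conductances are what the protocols quote). The peak occurs at
#' t = ln(tau_off/tau_on) * tau_on * tau_off / (tau_off - tau_on).
#'
#' @param t_since_event time since the event (ms); vectorised
#' @param tau_on,tau_off onset/offset time constants (ms), tau_on < tau_off
#' @param g_max peak conductance (nS)
#' @return conductance in nS
#' @export
dual_exp_conductance <- function(t_since_event, tau_on = 0.5, tau_off = 10,
                                 g_max = 5) {
  if (tau_on >= tau_off) stop("tau_on must be < tau_off")
  tp <- log(tau_off / tau_on) * tau_on * tau_off / (tau_off - tau_on)
  norm <- 1 / (exp(-tp / tau_off) - exp(-tp / tau_on))
  ifelse(t_since_event < 0, 0,
         g_max * norm * (exp(-t_since_event / tau_off) -
                         exp(-t_since_event / tau_on)))
}

#' Split a synaptic conductance into its Na+ and K+ components
#'
#' A glutamatergic conductance with reversal E_rev strictly between E_K and
#' E_Na is decomposed into fixed fractions g_Na/g = (E_rev - E_K)/(E_Na -
#' E_K) and g_K = g - g_Na (determined once, from the resting
#' concentrations). The Na+ component feeds the Na+ accumulation.
#'
#' @param g total synaptic conductance (nS)
#' @param V membrane potential (mV)
#' @param E_rev synaptic reversal potential (mV)
#' @param E_Na,E_K ionic reversal potentials (mV)
#' @return list with `I_Na`, `I_K` (nA, outward positive) and the
#'   conductance fractions `g_Na`, `g_K` (nS)
#' @export
split_synaptic_current <- function(g, V, E_rev, E_Na, E_K) {
  if (E_rev <= E_K || E_rev >= E_Na) stop("E_rev must lie in (E_K, E_Na)")
  g_Na <- g * (E_rev - E_K) / (E_Na - E_K)
  g_K <- g - g_Na
  list(I_Na = 1e-3 * g_Na * (V - E_Na), I_K = 1e-3 * g_K * (V - E_K),
       g_Na = g_Na, g_K = g_K)
}

#' Current-pulse train
#'
#' @param frequency pulse rate (Hz)
#' @param duration train duration (s)
#' @param amp pulse amplitude (nA)
#' @param width pulse width (ms)
#' @param seg target segment id
#' @param t0 train onset (ms)
#' @param holding constant holding current (nA) applied for `hold_until` ms
#'   from t = 0 (e.g. to suppress spontaneous firing)
#' @param hold_until end of the holding current (ms)
#' @return pulses data.frame for [protocol()]
#' @export
make_pulse_train <- function(frequency, duration, amp, width = 3, seg = 1L,
                             t0 = 0, holding = 0, hold_until = Inf) {
  stopifnot(frequency > 0)
  onsets <- t0 + seq(0, by = 1000 / frequency,
                     length.out = round(frequency * duration))
  df <- data.frame(on = onsets, off = onsets + width, amp = amp, seg = seg)
  if (holding != 0) {
    df <- rbind(df, data.frame(on = 0, off = hold_until, amp = holding,
                               seg = seg))
  }
  df
}

#' Synaptic event train at one site
#'
#' @param frequency event rate (Hz)
#' @param duration train duration (s)
#' @param seg target segment id
#' @param t0 onset (ms)
#' @param probe_after extra isolated probe events, offsets in ms after the
#'   *end* of the train (the prolonged-influence probes)
#' @param g_max,tau_on,tau_off,E_rev synapse parameters (nS, ms, ms, mV)
#' @return events data.frame for [protocol()]
#' @export
make_synaptic_train <- function(frequency, duration, seg, t0 = 0,
                                probe_after = numeric(0), g_max = 5,
                                tau_on = 0.5, tau_off = 10, E_rev = 10) {
  times <- t0 + seq(0, by = 1000 / frequency,
                    length.out = round(frequency * duration))
  t_end <- t0 + duration * 1000
  times <- c(times, t_end + probe_after)
  data.frame(time = times, seg = seg, g_max = g_max, tau_on = tau_on,
             tau_off = tau_off, E_rev = E_rev)
}

#' Climbing-fiber volley
#'
#' One concurrent event on every dendritic segment thicker than 2.2 um,
#' with the summed peak conductance fixed at `g_total` and distributed
#' across the qualifying segments in proportion to membrane area.
#'
#' @param m a [morphology()]
#' @param t event time(s), ms (vectorised: one volley per element)
#' @param g_total summed peak conductance (nS)
#' @param tau_on,tau_off,E_rev synapse parameters
#' @param min_diam qualifying diameter threshold (um)
#' @return events data.frame (zero rows, with a warning, if no segment
#'   qualifies)
#' @export
make_climbing_fiber_event <- function(m, t, g_total = 250, tau_on = 0.5,
                                      tau_off = 5, E_rev = 10,
                                      min_diam = 2.2) {
  s <- m$segments
  dend <- s$region %in% c("dendrite_proximal", "dendrite_distal", "tuft")
  q <- dend & s$diam > min_diam
  if (!any(q)) {
    warning("no dendritic segment thicker than ", min_diam,
            " um; empty climbing-fiber volley")
    return(data.frame(time = numeric(0), seg = integer(0), g_max = numeric(0),
                      tau_on = numeric(0), tau_off = numeric(0),
                      E_rev = numeric(0)))
  }
  area <- segment_geometry(s$length[q], s$diam[q])$lateral_area
  g <- g_total * area / sum(area)
  do.call(rbind, lapply(t, function(tt) {
    data.frame(time = tt, seg = s$id[q], g_max = g, tau_on = tau_on,
               tau_off = tau_off, E_rev = E_rev)
  }))
}

#' Distributed-input specification
#'
#' Defaults follow the distributed-input protocol: 1,000 "cortical"
#' Poisson trains at 1 Hz with 5 uniformly placed contacts each, and 1,000
#' "thalamic" trains at 1 Hz background with 5 Hz epochs, their contacts
#' drawn by path distance from a gamma(k = 2, theta = 60 um) density
#' (clustered: all 5 on one segment). Synapses are weak/slow (0.5 nS peak,
#' 15 ms decay).
#'
#' @param n_cortical,n_thalamic numbers of presynaptic trains
#' @param rate_background,rate_epoch rates (Hz)
#' @param epochs data.frame with `start` and `duration` (s) of the elevated
#'   thalamic episodes
#' @param contacts_per_train contacts per presynaptic train
#' @param gamma_k,gamma_theta gamma placement parameters (shape,
#'   scale in um)
#' @param clustered co-locate all of a thalamic train's contacts
#' @param g_max,tau_on,tau_off,E_rev synapse parameters
#' @export
distributed_input_spec <- function(n_cortical = 1000, n_thalamic = 1000,
                                   rate_background = 1, rate_epoch = 5,
                                   epochs = data.frame(start = c(2, 8, 14),
                                                       duration = 2.5),
                                   contacts_per_train = 5, gamma_k = 2,
                                   gamma_theta = 60, clustered = TRUE,
                                   g_max = 0.5, tau_on = 0.5, tau_off = 15,
                                   E_rev = 10) {
  stopifnot(rate_background >= 0, rate_epoch >= 0, contacts_per_train >= 1)
  structure(as.list(environment()), class = "distributed_input_spec")
}

## homogeneous Poisson event times on [0, t_stop] ms, rate in Hz
.poisson_train <- function(rate, t_stop_ms) {
  if (rate <= 0) return(numeric(0))
  n <- stats::rpois(1, rate * t_stop_ms / 1000)
  sort(stats::runif(n, 0, t_stop_ms))
}

#' Generate a distributed synaptic event schedule
#'
#' Cortical trains are homogeneous Poisson processes; thalamic trains are
#' piecewise-homogeneous (background rate outside the epochs, epoch rate
#' inside). Cortical contacts are placed uniformly by membrane area over
#' the dendrites; thalamic contacts by sampling a path distance from
#' gamma(k, theta), truncated to the dendritic extent by resampling, and
#' mapping it to the nearest dendritic segment. The schedule is a
#' deterministic function of (spec, morphology, seed, t_stop).
#'
#' @param spec a [distributed_input_spec()]
#' @param m a [morphology()]
#' @param t_stop schedule span (ms)
#' @param seed RNG seed
#' @return events data.frame for [protocol()], with a `train` column
#' @export
make_distributed_input <- function(spec, m, t_stop, seed) {
  if (nrow(spec$epochs) &&
      any((spec$epochs$start + spec$epochs$duration) * 1000 > t_stop)) {
    stop("thalamic epoch window extends beyond the simulation span")
  }
  s <- m$segments
  dend <- which(s$region %in% c("dendrite_proximal", "dendrite_distal", "tuft"))
  if (!length(dend)) stop("morphology has no dendrites")
  area <- segment_geometry(s$length[dend], s$diam[dend])$lateral_area
  ## gamma placement distances are measured into the dendritic tree (from
  ## the point where the dendrites leave the soma), so a small sampled
  ## distance means a proximal contact
  pdist <- path_distance(m)[dend]
  pdist <- pdist - min(pdist - s$length[dend] / 2)
  max_ext <- max(pdist)
  out <- withr_seed(seed, {
    res <- list()
    for (k in seq_len(spec$n_cortical)) {
      times <- .poisson_train(spec$rate_background, t_stop)
      if (!length(times)) next
      sites <- dend[sample.int(length(dend), spec$contacts_per_train,
                               replace = TRUE, prob = area)]
      res[[length(res) + 1L]] <-
        data.frame(time = rep(times, each = length(sites)),
                   seg = rep(s$id[sites], length(times)),
                   train = paste0("ctx", k))
    }
    for (k in seq_len(spec$n_thalamic)) {
      times <- .thalamic_train(spec, t_stop)
      if (!length(times)) next
      nsite <- if (spec$clustered) 1L else spec$contacts_per_train
      d <- numeric(nsite)
      for (j in seq_len(nsite)) {
        repeat {
          d[j] <- stats::rgamma(1, shape = spec$gamma_k,
                                scale = spec$gamma_theta)
          if (d[j] <= max_ext) break
        }
      }
      sites <- dend[vapply(d, function(x) which.min(abs(pdist - x)),
                           integer(1))]
      sites <- rep(sites, length.out = spec$contacts_per_train)
      res[[length(res) + 1L]] <-
        data.frame(time = rep(times, each = length(sites)),
                   seg = rep(s$id[sites], length(times)),
                   train = paste0("thal", k))
    }
    res
  })
  if (!length(out)) {
    return(data.frame(time = numeric(0), seg = integer(0), g_max = numeric(0),
                      tau_on = numeric(0), tau_off = numeric(0),
                      E_rev = numeric(0), train = character(0)))
  }
  ev <- do.call(rbind, out)
  ev$g_max <- spec$g_max
  ev$tau_on <- spec$tau_on
  ev$tau_off <- spec$tau_off
  ev$E_rev <- spec$E_rev
  ev[order(ev$time), c("time", "seg", "g_max", "tau_on", "tau_off", "E_rev",
                       "train")]
}

## piecewise-homogeneous Poisson times for a thalamic train (ms)
.thalamic_train <- function(spec, t_stop) {
  bounds <- c(0, t(cbind(spec$epochs$start,
                         spec$epochs$start + spec$epochs$duration)) * 1000,
              t_stop)
  times <- numeric(0)
  for (i in seq_len(length(bounds) - 1)) {
    rate <- if (i %% 2 == 0) spec$rate_epoch else spec$rate_background
    span <- bounds[i + 1] - bounds[i]
    if (span <= 0) next
    n <- stats::rpois(1, rate * span / 1000)
    times <- c(times, stats::runif(n, bounds[i], bounds[i + 1]))
  }
  sort(times)
}

## run code with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Calibrate the pulse amplitude for one-spike-per-pulse firing
#'
#' Binary search for the smallest pulse amplitude such that a short test
#' train evokes exactly one action potential per pulse, reproducing the
#' adjust-until-one-spike-per-pulse convention of the pulse-train
#' protocols.
#'
#' @param model a [neuron_model()]
#' @param frequency train frequency (Hz)
#' @param width pulse width (ms)
#' @param seg stimulated segment id (default soma)
#' @param n_test number of test pulses
#' @param lo,hi search bracket (nA)
#' @param holding holding current (nA)
#' @param tol bracket tolerance (nA)
#' @return calibrated amplitude (nA)
#' @export
calibrate_pulse_amplitude <- function(model, frequency = 30, width = 3,
                                      seg = NULL, n_test = 5, lo = 0.01,
                                      hi = 5, holding = 0, tol = 0.01) {
  if (is.null(seg)) seg <- model$segments$id[segment_index(model, region = "soma")]
  count <- function(amp) {
    pt <- make_pulse_train(frequency, n_test / frequency, amp, width, seg,
                           holding = holding)
    tr <- run_protocol(model, protocol(t_stop = n_test * 1000 / frequency + 50,
                                       pulses = pt),
                       solver_config(record_every = 40L))
    length(tr$spike_times)
  }
  if (count(hi) < n_test) stop("upper bracket does not evoke one spike per pulse")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count(mid) >= n_test) hi <- mid else lo <- mid
  }
  ## final check at the returned amplitude: exactly one spike per pulse
  if (count(hi) != n_test) {
    stop("no amplitude in bracket gives exactly one spike per pulse")
  }
  hi
}
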