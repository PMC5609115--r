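## Protocol driver: stimulus assembly, the call into the C++ core, and the
## simulation-trace container.

#' Solver configuration
#'
#' @param dt time step (ms). 0.025 ms resolves the spike upstroke with the
#'   backward-Euler voltage solve; concentrations are split off after the
#'   voltage update (their time scales are seconds, so the splitting error
#'   is negligible).
#' @param record_every record every this many steps
#' @param spike_threshold detection threshold (mV): upward crossing with a
#'   1 ms refractory period
#' @export
solver_config <- function(dt = 0.025, record_every = 8L,
                          spike_threshold = 0) {
  stopifnot(dt > 0, record_every >= 1)
  list(dt = dt, record_every = as.integer(record_every),
       spike_threshold = spike_threshold)
}

#' Stimulation protocol
#'
#' @param t_stop total simulated time (ms)
#' @param pulses data.frame with columns `on`, `off` (ms), `amp` (nA),
#'   `seg` (segment id); or NULL
#' @param events synaptic event schedule: data.frame with columns `time`
#'   (ms), `seg` (segment id), `g_max` (nS), `tau_on`, `tau_off` (ms),
#'   `E_rev` (mV); or NULL
#' @param clamp somatic voltage-clamp command: data.frame with columns `t`
#'   (ms, step times) and `V` (mV) plus attribute-free `seg` argument; or NULL
#' @param clamp_seg segment id to clamp
#' @export
protocol <- function(t_stop, pulses = NULL, events = NULL, clamp = NULL,
                     clamp_seg = NULL) {
  stopifnot(t_stop > 0)
  if (!is.null(events) && nrow(events)) {
    if (any(events$tau_on >= events$tau_off)) {
      stop("synaptic events need tau_on < tau_off")
    }
    if (any(events$time < 0 | events$time > t_stop)) {
      stop("synaptic event outside the simulation span")
    }
  }
  structure(list(t_stop = t_stop, pulses = pulses, events = events,
                 clamp = clamp, clamp_seg = clamp_seg), class = "protocol")
}

## group synaptic events into (segment, kinetics, reversal) instances
.build_syn <- function(events, model) {
  if (is.null(events) || nrow(events) == 0L) {
    return(list(inst = data.frame(seg0 = integer(0), tau_on = numeric(0),
                                  tau_off = numeric(0), E_rev = numeric(0),
                                  na_frac = numeric(0), norm = numeric(0)),
                ev = data.frame(inst0 = integer(0), time = numeric(0),
                                weight = numeric(0))))
  }
  mech <- model$mech
  seg_row <- vapply(events$seg, function(id) segment_index(model, id = id),
                    integer(1))
  E_Na_rest <- nernst(mech$Na_init, mech$Na_o, 1, mech$T_K)
  if (any(events$E_rev <= mech$E_K | events$E_rev >= E_Na_rest)) {
    stop("synaptic E_rev must lie in (E_K, E_Na)")
  }
  key <- paste(seg_row, events$tau_on, events$tau_off, events$E_rev)
  uk <- !duplicated(key)
  inst <- data.frame(seg0 = seg_row[uk] - 1L,
                     tau_on = events$tau_on[uk],
                     tau_off = events$tau_off[uk],
                     E_rev = events$E_rev[uk])
  inst$na_frac <- (inst$E_rev - mech$E_K) / (E_Na_rest - mech$E_K)
  tp <- log(inst$tau_off / inst$tau_on) * inst$tau_on * inst$tau_off /
    (inst$tau_off - inst$tau_on)
  inst$norm <- 1 / (exp(-tp / inst$tau_off) - exp(-tp / inst$tau_on))
  imap <- match(key, key[uk])
  ord <- order(events$time)
  list(inst = inst,
       ev = data.frame(inst0 = imap[ord] - 1L, time = events$time[ord],
                       weight = events$g_max[ord]))
}

#' Run a stimulation protocol
#'
#' Deterministic given the model, protocol and solver configuration: any
#' randomness lives in protocol *generation* (see
#' [make_distributed_input()]), never in the integrator, so identical
#' schedules give bit-identical traces.
#'
#' @param model a [neuron_model()]
#' @param proto a [protocol()]
#' @param solver a [solver_config()]
#' @param state optional initial-state override: list with any of `V`,
#'   `Na`, `Ca` (scalar or per-segment, solver order)
#' @param detect_seg segment id used for spike detection (default: soma)
#' @return a `sim_trace`
#' @export
run_protocol <- function(model, proto, solver = solver_config(),
                         state = NULL, detect_seg = NULL) {
  cm <- compile_model(model, state)
  n_steps <- ceiling(proto$t_stop / solver$dt)
  n_steps <- as.integer(ceiling(n_steps / solver$record_every) *
                        solver$record_every)
  pulses <- proto$pulses
  if (is.null(pulses)) pulses <- data.frame(on = numeric(0), off = numeric(0),
                                            amp = numeric(0), seg = integer(0))
  pseg <- vapply(pulses$seg, function(id) segment_index(model, id = id),
                 integer(1)) - 1L
  syn <- .build_syn(proto$events, model)
  if (!is.null(proto$clamp)) {
    cseg <- segment_index(model, id = proto$clamp_seg) - 1L
    ct <- proto$clamp$t; cv <- proto$clamp$V
  } else {
    cseg <- -1L; ct <- 0; cv <- 0
  }
  det <- if (is.null(detect_seg)) segment_index(model, region = "soma")
         else segment_index(model, id = detect_seg)
  stim <- list(pulse_on = as.numeric(pulses$on),
               pulse_off = as.numeric(pulses$off),
               pulse_amp = as.numeric(pulses$amp),
               pulse_seg = as.integer(pseg),
               syn_seg = as.integer(syn$inst$seg0),
               syn_tau_on = syn$inst$tau_on, syn_tau_off = syn$inst$tau_off,
               syn_E_rev = syn$inst$E_rev, syn_na_frac = syn$inst$na_frac,
               syn_norm = syn$inst$norm,
               ev_inst = as.integer(syn$ev$inst0), ev_time = syn$ev$time,
               ev_weight = syn$ev$weight,
               clamp_seg = as.integer(cseg), clamp_t = as.numeric(ct),
               clamp_v = as.numeric(cv))
  ctrl <- list(dt = solver$dt, n_steps = n_steps,
               record_every = solver$record_every,
               detect_seg = as.integer(det - 1L),
               spike_threshold = solver$spike_threshold)
  out <- .sim_core(cm, stim, ctrl)
  structure(c(out,
              list(seg_id = model$segments$id,
                   region = model$segments$region, dt = solver$dt,
                   area = model$geometry$lateral_area,
                   volume = model$geometry$volume)),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("<sim_trace> ", length(x$t), " samples x ", ncol(x$V), " segments, ",
      "t = [0, ", max(x$t), "] ms, ", length(x$spike_times), " spikes\n",
      sep = "")
  invisible(x)
}

#' Extract one recorded variable at one segment
#'
#' @param trace a `sim_trace`
#' @param var one of `"V"`, `"Na"`, `"Ca"`, `"I_pump"`
#' @param seg segment id (or NULL with `region`)
#' @param region region tag (see [segment_index()])
#' @param which passed to [segment_index()]
#' @return data.frame with columns `t` and `value`
#' @export
trace_at <- function(trace, var = c("V", "Na", "Ca", "I_pump"), seg = NULL,
                     region = NULL, which = "first") {
  var <- match.arg(var)
  i <- if (!is.null(seg)) match(seg, trace$seg_id)
       else {
         hits <- which(trace$region == region)
         if (!length(hits)) stop("no segment tagged '", region, "'")
         switch(which, first = hits[1], last = hits[length(hits)],
                mid = hits[ceiling(length(hits) / 2)])
       }
  if (is.na(i)) stop("no such segment in trace")
  data.frame(t = trace$t, value = trace[[var]][, i])
}

#' Long-format view of a trace
#' @param x a `sim_trace`
#' @param vars variables to include
#' @param ... unused
#' @export
as.data.frame.sim_trace <- function(x, vars = c("V", "Na", "Ca"), ...) {
  do.call(rbind, lapply(vars, function(v) {
    do.call(rbind, lapply(seq_along(x$seg_id), function(i) {
      data.frame(time = x$t, segment = x$seg_id[i], variable = v,
                 value = x[[v]][, i])
    }))
  }))
}

#' Write / read a trace as CSV (long format)
#'
#' A plain-text round-trippable export of the recorded variables; the
#' header line carries the time step.
#'
#' @param trace a `sim_trace`
#' @param path file path
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  con <- file(path, "w")
  writeLines(sprintf("# nadyn trace dt=%g", trace$dt), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Advance a model state by a single time step
#'
#' Thin single-step wrapper around the integrator, mainly for tests of the
#' stepping contract. Gating variables are taken at their steady state for
#' the supplied voltage.
#'
#' @param model a [neuron_model()]
#' @param state list with `V`, `Na`, `Ca` (scalars or per-segment vectors)
#' @param dt time step (ms)
#' @return updated state list
#' @export
step_state <- function(model, state, dt) {
  tr <- run_protocol(model, protocol(t_stop = dt),
                     solver_config(dt = dt, record_every = 1L), state = state)
  k <- length(tr$t)
  list(V = tr$V[k, ], Na = tr$Na[k, ], Ca = tr$Ca[k, ])
}
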