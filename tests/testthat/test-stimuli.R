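test_that("dual-exponential waveform is normalised and peaks where calculus says", {
  # peak time ln(tau_off/tau_on) tau_on tau_off / (tau_off - tau_on)
  tp <- log(10 / 0.5) * 0.5 * 10 / (10 - 0.5)
  expect_equal(tp, 1.577, tolerance = 1e-3)
  expect_equal(dual_exp_conductance(tp, 0.5, 10, g_max = 5), 5,
               tolerance = 1e-12)
  expect_equal(dual_exp_conductance(0, 0.5, 10), 0)
  expect_equal(dual_exp_conductance(-3, 0.5, 10), 0)
  # peak equals g_max for any tau pair (normalisation contract)
  for (taus in list(c(0.2, 2), c(1, 30), c(0.5, 15))) {
    tpk <- log(taus[2] / taus[1]) * prod(taus) / diff(taus)
    g <- dual_exp_conductance(seq(0, 100, by = 1e-3), taus[1], taus[2],
                              g_max = 3.3)
    expect_equal(max(g), 3.3, tolerance = 1e-6)
    expect_equal(dual_exp_conductance(tpk, taus[1], taus[2], 3.3), 3.3)
  }
  expect_error(dual_exp_conductance(1, 10, 0.5), "tau_on")
})

test_that("synaptic conductance splits by the reversal condition", {
  s <- split_synaptic_current(3, V = -60, E_rev = 10, E_Na = 60, E_K = -90)
  expect_equal(s$g_Na / 3, 100 / 150)  # (E_rev - E_K)/(E_Na - E_K) = 2/3
  expect_equal(s$g_Na + s$g_K, 3)
  # at V = E_rev the total current vanishes, the components do not
  s2 <- split_synaptic_current(3, V = 10, E_rev = 10, E_Na = 60, E_K = -90)
  expect_equal(s2$I_Na + s2$I_K, 0, tolerance = 1e-15)
  expect_lt(s2$I_Na, 0)
  expect_gt(s2$I_K, 0)
  # boundary: E_rev -> E_K means no Na component
  s3 <- split_synaptic_current(3, -60, E_rev = -90 + 1e-9, E_Na = 60,
                               E_K = -90)
  expect_equal(s3$g_Na, 0, tolerance = 1e-9)
  expect_error(split_synaptic_current(3, -60, E_rev = 80, E_Na = 60,
                                      E_K = -90), "E_rev")
})

test_that("climbing-fiber volleys target thick dendrites with conserved total conductance", {
  m <- build_archetype("purkinje_like")
  ev <- make_climbing_fiber_event(m, t = 100)
  expect_true(all(ev$time == 100))
  expect_equal(sum(ev$g_max), 250, tolerance = 1e-12)
  s <- m$segments
  expect_true(all(s$diam[match(ev$seg, s$id)] > 2.2))
  # proportional to area: equal-geometry segments get equal shares
  areas <- segment_geometry(s$length[match(ev$seg, s$id)],
                            s$diam[match(ev$seg, s$id)])$lateral_area
  expect_equal(ev$g_max / areas, rep(ev$g_max[1] / areas[1], nrow(ev)),
               tolerance = 1e-12)
  # a morphology with only thin dendrites gives an empty volley
  thin <- build_archetype("pyramidal_like", params = list(prox_d = 1.5))
  expect_warning(ev0 <- make_climbing_fiber_event(thin, 100), "empty")
  expect_equal(nrow(ev0), 0L)
})

test_that("distributed input reproduces its Poisson and gamma statistics", {
  m <- build_archetype("pyramidal_like", spatial_resolution = 2L)
  spec <- distributed_input_spec(n_cortical = 1000, n_thalamic = 0,
                                 contacts_per_train = 1)
  t_stop <- 20000
  ev <- make_distributed_input(spec, m, t_stop, seed = 11)
  # empirical mean rate of the cortical trains: 1 Hz within 3 s.e.
  n_ev <- nrow(ev)
  expected <- 1000 * 1 * t_stop / 1000
  se <- sqrt(expected)
  expect_lt(abs(n_ev - expected), 3 * se)

  # thalamic gamma placement: mean path distance ~ k theta before truncation
  big <- build_archetype("pyramidal_like",
                         params = list(dist_L = 1200, dist_n = 24))
  spec2 <- distributed_input_spec(n_cortical = 0, n_thalamic = 400,
                                  clustered = FALSE, contacts_per_train = 5,
                                  epochs = data.frame(start = 0.5,
                                                      duration = 0.5))
  ev2 <- make_distributed_input(spec2, big, 3000, seed = 12)
  pd <- path_distance(big)
  dend <- grepl("dendrite|tuft", big$segments$region)
  pd <- pd - min((pd - big$segments$length / 2)[dend])
  # average over all contact rows (event counts are independent of
  # location, so this is an unbiased estimate of the placement mean)
  d_sites <- pd[match(ev2$seg, big$segments$id)]
  expect_equal(mean(d_sites), 2 * 60, tolerance = 0.1)

  # clustered thalamic trains put all contacts on one segment
  spec3 <- distributed_input_spec(n_cortical = 0, n_thalamic = 30,
                                  clustered = TRUE, contacts_per_train = 5,
                                  epochs = data.frame(start = 1,
                                                      duration = 1))
  ev3 <- make_distributed_input(spec3, m, 5000, seed = 13)
  per_train <- split(ev3$seg, ev3$train)
  expect_true(all(vapply(per_train, function(x) length(unique(x)) == 1L,
                         logical(1))))

  # determinism: same (spec, morphology, seed) -> identical schedule
  ev_a <- make_distributed_input(spec3, m, 5000, seed = 99)
  ev_b <- make_distributed_input(spec3, m, 5000, seed = 99)
  expect_identical(ev_a, ev_b)
  expect_false(identical(
    make_distributed_input(spec3, m, 5000, seed = 100)$time, ev_a$time))
  # epochs outside the span are rejected
  expect_error(make_distributed_input(
    distributed_input_spec(epochs = data.frame(start = 10, duration = 5)),
    m, 5000, seed = 1), "beyond the simulation span")
})

test_that("thalamic epochs elevate the event rate inside the window", {
  m <- build_archetype("pyramidal_like")
  spec <- distributed_input_spec(n_cortical = 0, n_thalamic = 500,
                                 rate_background = 1, rate_epoch = 5,
                                 epochs = data.frame(start = 2,
                                                     duration = 2),
                                 contacts_per_train = 1)
  ev <- make_distributed_input(spec, m, 8000, seed = 21)
  r_bg <- sum(ev$time < 2000) / 2 / 500
  r_ep <- sum(ev$time >= 2000 & ev$time < 4000) / 2 / 500
  expect_equal(r_bg, 1, tolerance = 0.15)
  expect_equal(r_ep, 5, tolerance = 0.15)
})

test_that("synaptic sodium feeds accumulation consistently with charge bookkeeping", {
  # diffusion-free single compartment: the local [Na+]i rise equals the
  # integrated synaptic Na+ charge / (F V) computed independently
  morph <- morphology(data.frame(id = 1L, parent = NA, length = 20,
                                 diam = 10, region = "soma"))
  mech <- mechanism_set(
    channels = list(channel_spec("leak", "nonspecific", 2e-4,
                                 driving = "fixed", E_fix = -65)),
    na_pump = pump_spec(0, 0, 0, 0, density = 0),
    ca_pump = pump_spec(0, 0, 0, 0, density = 0),
    ncx = ncx_spec(I_max = 0), buffer = NULL, V_init = -65)
  model <- neuron_model(morph, mech)
  ev <- make_synaptic_train(10, 0.5, seg = 1L, t0 = 10, g_max = 2)
  tr <- run_protocol(model, protocol(t_stop = 600, events = ev),
                     solver_config(record_every = 1L))
  k <- length(tr$t)
  vol <- tr$volume[1]
  rise_sim <- tr$Na[k, 1] - tr$Na[1, 1]
  # independent mass-balance oracle from the recorded charge integral
  rise_oracle <- -tr$cum_I_Na[k] * (1e6 / 96485.33212) / vol
  expect_equal(rise_sim, rise_oracle, tolerance = 1e-6 * abs(rise_sim))
  expect_gt(rise_sim, 0)
})

test_that("pulse-amplitude calibration finds one spike per pulse", {
  model <- fixture("mitral", function() build_model("mitral_like"))
  amp <- calibrate_pulse_amplitude(model, 30, 3, n_test = 4, tol = 0.02)
  pt <- make_pulse_train(30, 4 / 30, amp, 3, 1L)
  tr <- run_protocol(model, protocol(t_stop = 200, pulses = pt),
                     solver_config(record_every = 40L))
  expect_equal(length(tr$spike_times), 4L)
  # just below the calibrated amplitude at least one pulse fails
  pt2 <- make_pulse_train(30, 4 / 30, amp - 0.03, 3, 1L)
  tr2 <- run_protocol(model, protocol(t_stop = 200, pulses = pt2),
                      solver_config(record_every = 40L))
  expect_lt(length(tr2$spike_times), 4L)
})
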