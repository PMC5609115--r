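test_that("steady state of a stimulated passive cable matches cable theory", {
  n <- 50; L <- 20; d <- 2; gleak <- 2e-4; Ra <- 150; E <- -65
  model <- passive_cable(n = n, L = L, d = d, gleak = gleak, E_leak = E,
                         Ra = Ra)
  I0 <- 0.05  # nA into the first segment
  tr <- run_protocol(model,
                     protocol(t_stop = 400,
                              pulses = data.frame(on = 0, off = 400,
                                                  amp = I0, seg = 1L)),
                     solver_config(dt = 0.05, record_every = 400L))
  v <- tr$V[nrow(tr$V), ] - E
  # analytic sealed-end cable: V(x) proportional to cosh((L_tot - x)/lambda)
  lambda_um <- sqrt((1 / gleak) * (d * 1e-4) / (4 * Ra)) * 1e4
  x <- (seq_len(n) - 0.5) * L
  shape <- cosh((n * L - x) / lambda_um)
  pred <- v[1] * shape / shape[1]
  expect_lt(max(abs(v - pred) / v[1]), 0.01)
  # input resistance at the injection point (the first segment centre,
  # x0 = L/2): r_a lambda cosh((L_tot - x0)/lambda) cosh(x0/lambda) /
  # sinh(L_tot/lambda), within 1 %
  area_cross_cm2 <- pi * (d * 1e-4)^2 / 4
  x0 <- L / 2
  r_in_MOhm <- (Ra * lambda_um * 1e-4 / area_cross_cm2) * 1e-6 *
    cosh((n * L - x0) / lambda_um) * cosh(x0 / lambda_um) /
    sinh(n * L / lambda_um)
  expect_equal(v[1] / I0, r_in_MOhm, tolerance = 0.01)
})

test_that("a resting model is a fixed point of the stepper", {
  model <- fixture("mitral", function() build_model("mitral_like"))
  settle <- run_protocol(model, protocol(t_stop = 1500),
                         solver_config(record_every = 200L))
  k <- nrow(settle$V)
  st <- list(V = settle$V[k, ], Na = settle$Na[k, ], Ca = settle$Ca[k, ])
  tr <- run_protocol(model, protocol(t_stop = 100),
                     solver_config(record_every = 40L), state = st)
  expect_lt(max(abs(tr$V[nrow(tr$V), ] - st$V)), 0.5)
  expect_lt(max(abs(tr$Na[nrow(tr$Na), ] - st$Na)), 0.05)
  expect_lt(max(abs(tr$Ca[nrow(tr$Ca), ] - st$Ca)) / min(st$Ca), 0.05)
})

test_that("halving dt moves the first spike peak by less than dt", {
  model <- fixture("mitral", function() build_model("mitral_like"))
  peak_time <- function(dt) {
    tr <- run_protocol(model,
                       protocol(t_stop = 60,
                                pulses = data.frame(on = 10, off = 13,
                                                    amp = 1, seg = 1L)),
                       solver_config(dt = dt, record_every = 1L))
    v <- trace_at(tr, "V", region = "soma")
    v$t[which.max(v$value)]
  }
  t1 <- peak_time(0.025)
  t2 <- peak_time(0.0125)
  expect_lt(abs(t1 - t2), 0.025)
})

test_that("runs are deterministic and invariant to segment reordering", {
  m1 <- build_model("pyramidal_like")
  ev <- make_synaptic_train(10, 0.4, seg = max(m1$segments$id), t0 = 20)
  proto <- protocol(t_stop = 600, events = ev,
                    pulses = data.frame(on = 100, off = 103, amp = 0.8,
                                        seg = 1L))
  sv <- solver_config(record_every = 20L)
  tr_a <- run_protocol(m1, proto, sv)
  tr_b <- run_protocol(m1, proto, sv)
  expect_identical(tr_a$V, tr_b$V)
  expect_identical(tr_a$Na, tr_b$Na)
  expect_identical(tr_a$spike_times, tr_b$spike_times)
  # permute the segment rows of the morphology; traces must agree by id
  s <- m1$morph$segments
  set.seed(1)
  perm <- sample(nrow(s))
  m2 <- neuron_model(morphology(s[perm, ]), m1$mech)
  tr_c <- run_protocol(m2, proto, sv)
  for (id in s$id) {
    expect_equal(trace_at(tr_c, "V", seg = id)$value,
                 trace_at(tr_a, "V", seg = id)$value, tolerance = 1e-10)
  }
})

test_that("empty protocol on a model raises errors only where promised", {
  model <- passive_single()
  tr <- run_protocol(model, protocol(t_stop = 50))
  expect_equal(length(tr$spike_times), 0L)
  expect_true(all(abs(tr$V - (-65)) < 1e-6))
  expect_error(trace_at(tr, "V", seg = 999), "no such segment")
  expect_error(protocol(t_stop = 100,
                        events = data.frame(time = 500, seg = 1, g_max = 1,
                                            tau_on = 0.5, tau_off = 10,
                                            E_rev = 10)),
               "outside the simulation span")
})

test_that("sodium mass balance closes over an active run", {
  model <- fixture("mitral", function() build_model("mitral_like"))
  pt <- make_pulse_train(30, 0.5, 0.6, 3, 1L, t0 = 20)
  tr <- run_protocol(model, protocol(t_stop = 1000, pulses = pt),
                     solver_config(record_every = 40L))
  vol <- tr$volume
  amount0 <- sum(tr$Na[1, ] * vol)
  amountT <- sum(tr$Na[nrow(tr$Na), ] * vol)
  # nA ms -> mM um^3 (monovalent): x 1e6 / F
  conv <- 1e6 / 96485.33212
  k <- length(tr$t)
  predicted <- -(tr$cum_I_Na[k] + 3 * tr$cum_I_pump[k]) * conv
  expect_equal(amountT - amount0, predicted,
               tolerance = 0.005 * abs(amountT - amount0))
  expect_gt(amountT, amount0)  # the train loaded the cell
})

test_that("solver reports divergence with the failure time", {
  # absurd overdrive: gigantic current into a tiny compartment
  model <- passive_single()
  expect_error(
    run_protocol(model,
                 protocol(t_stop = 50,
                          pulses = data.frame(on = 0, off = 50, amp = Inf,
                                              seg = 1L)),
                 solver_config(dt = 0.5)),
    "divergence|non-finite")
})
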