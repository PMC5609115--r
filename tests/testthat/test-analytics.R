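test_that("detect_spikes and rate_histogram count correctly", {
  t <- seq(0, 100, by = 0.1)
  V <- rep(-65, length(t))
  for (t0 in c(10, 30, 50)) V[t >= t0 & t < t0 + 1] <- 20
  idx <- detect_spikes(t, V)
  expect_equal(length(idx), 3L)
  expect_equal(t[idx], c(10, 30, 50), tolerance = 0.11)
  # refractory merges crossings closer than 1 ms
  V2 <- rep(-65, length(t)); V2[t >= 10 & t < 10.3] <- 20
  V2[t >= 10.5 & t < 10.8] <- 20
  expect_equal(length(detect_spikes(t, V2)), 1L)

  h <- rate_histogram(seq(0, 1999, length.out = 60), bin_width = 1000,
                      t_stop = 2000)
  expect_equal(h$rate, c(30, 30))
  expect_equal(rate_histogram(numeric(0), 500, 2000)$rate, rep(0, 4))
  # averaging two identical runs equals one run
  st <- c(100, 900, 1500)
  h1 <- rate_histogram(st, 500, 2000)
  h2 <- rate_histogram(list(st, st), 500, 2000)
  expect_equal(h2$rate, h1$rate)
})

test_that("amplitude_series normalises to the first event", {
  t <- seq(0, 300, by = 0.05)
  V <- rep(-65, length(t))
  peaks <- c(10, 9, 8)
  for (i in 1:3) {
    t0 <- 50 * i
    win <- t >= t0 & t < t0 + 5
    V[win] <- -65 + peaks[i] * sin(pi * (t[win] - t0) / 5)
  }
  tr <- structure(list(t = t, V = matrix(V, ncol = 1), seg_id = 1L,
                       region = "soma"), class = "sim_trace")
  a <- amplitude_series(tr, "epsp", event_times = c(50, 100, 150), seg = 1L,
                        search_window = 10)
  expect_equal(a, c(1, 0.9, 0.8), tolerance = 1e-6)
  expect_equal(amplitude_series(tr, "epsp", event_times = 50, seg = 1L),
               1.0)
  expect_error(amplitude_series(tr, "epsp", seg = 1L), "event_times")
})

test_that("effective_capacitance recovers the textbook capacitor", {
  # 1000 um^2 at 1 uF/cm^2 -> 10 pF = 0.01 nF
  model <- passive_single()
  C <- effective_capacitance(model, -70, -60)
  expect_lt(abs(C - 0.01) / 0.01, 0.01)
  # independent of the holding pair in the passive range
  C2 <- effective_capacitance(model, -80, -65)
  expect_equal(C2, C, tolerance = 0.005)
  # doubling the membrane area doubles C
  model2 <- passive_single(L = 200)
  expect_equal(effective_capacitance(model2, -70, -60), 2 * C,
               tolerance = 0.01)
})

test_that("sodium entry ratio >= 1 and matches a brute-force integration oracle", {
  model <- fixture("mitral", function() build_model("mitral_like"))
  C <- effective_capacitance(model, -75, -65)
  tr <- run_protocol(model,
                     protocol(t_stop = 60,
                              pulses = data.frame(on = 10, off = 13,
                                                  amp = 1, seg = 1L)),
                     solver_config(record_every = 1L))
  ser <- sodium_entry_ratio(tr, C)
  expect_equal(length(ser), 1L)
  expect_gte(ser, 1)
  expect_lt(ser, 20)

  # oracle: independent trapezoid integration of the per-step Na+ current
  # over the same spike window
  v <- trace_at(tr, "V", region = "soma")
  i_na <- c(0, diff(tr$cum_I_Na)) / tr$dt      # nA at each sample
  i0 <- detect_spikes(v$t, v$value, threshold = -10)[1]
  j <- i0; while (v$value[j] >= -10) j <- j + 1L
  j <- j + round(2 / tr$dt)
  win <- i0:j
  q_oracle <- abs(sum((i_na[win][-1] + i_na[win][-length(win)]) / 2) *
                  tr$dt) * 1e-3                # nC
  amp <- max(v$value[win]) - v$value[1]
  ser_oracle <- 1000 * q_oracle / (amp * C)
  expect_equal(ser, ser_oracle, tolerance = 0.005 * ser_oracle)
  expect_error(sodium_entry_ratio(
    run_protocol(model, protocol(t_stop = 20),
                 solver_config(record_every = 1L)), C), "no spike")
})

test_that("stable_state_ca: closed form vs root finder on a Na grid", {
  ncx <- default_ncx(I_max = 0.05)
  cap <- default_ca_pump(); cap$density <- 2e-14
  grid <- seq(2, 60, length.out = 50)
  cf <- stable_state_ca(grid, V = -70, ncx = ncx, ca_pump = cap)
  rt <- stable_state_ca(grid, V = -70, ncx = ncx, ca_pump = cap,
                        method = "root")
  expect_lt(max(abs(cf - rt) / cf), 1e-8)
  # monotone increasing in Na_i
  expect_true(all(diff(cf) > 0))
  # zero-exchanger limit: the pump-only equilibrium Ca_o k2 k4/(k1 k3)
  ncx0 <- default_ncx(I_max = 0)
  eq <- 2 * cap$k2 * cap$k4 / (cap$k1 * cap$k3)
  expect_equal(stable_state_ca(20, -70, ncx0, cap), eq, tolerance = 1e-10)
  # 10x exchanger shifts the elevated-Na part of the curve up; 0.1x
  # flattens it toward the pump-only equilibrium (curves can cross at low
  # Na_i where the exchanger still runs forward)
  up <- default_ncx(I_max = 0.5); dn <- default_ncx(I_max = 0.005)
  hi_na <- grid[grid >= 15]
  expect_true(all(stable_state_ca(hi_na, -70, up, cap) >
                  stable_state_ca(hi_na, -70, ncx, cap)))
  lo <- stable_state_ca(hi_na, -70, dn, cap)
  expect_true(all(lo < stable_state_ca(hi_na, -70, ncx, cap)))
  expect_lt(diff(range(lo)) / diff(range(stable_state_ca(hi_na, -70, ncx,
                                                         cap))), 0.2)
})

test_that("E_Na curve is strictly decreasing and convex", {
  cur <- ena_curve(seq(5, 60, by = 0.5))
  expect_true(all(diff(cur$E_Na) < 0))
  expect_true(all(diff(diff(cur$E_Na)) > 0))
})

test_that("pump_curve exposes the specific-current relationship", {
  pc <- pump_curve(seq(0, 60, 1), default_na_pump(), density = 5e-12)
  expect_true(all(diff(pc$I_pump) >= 0))
  expect_lt(pc$I_pump[pc$Na_i == 10][1], 1e-12)
})
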