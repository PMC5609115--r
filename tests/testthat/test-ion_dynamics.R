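test_that("accumulation_rate does the dimensional bookkeeping", {
  # -1 nA (inward) into 1000 um^3 for 1 ms -> +1.0364e-2 mM
  expect_equal(accumulation_rate(-1, 1, 1000), 1.0364e-2, tolerance = 1e-4)
  expect_equal(accumulation_rate(0, 1, 500), 0)
  # doubling volume halves the rate; valence divides it
  expect_equal(accumulation_rate(-1, 1, 2000),
               accumulation_rate(-1, 1, 1000) / 2)
  expect_equal(accumulation_rate(-1, 2, 1000),
               accumulation_rate(-1, 1, 1000) / 2)
  expect_error(accumulation_rate(1, 1, 0), "volume")
})

test_that("diffusion_step conserves mass and symmetrises a two-segment load", {
  m <- morphology(data.frame(id = 1:2, parent = c(NA, 1), length = 10,
                             diam = 2, region = "soma"))
  spec <- diffusion_spec(D_Na = 0.3)
  conc <- c(10, 20)
  vol <- segment_geometry(10, 2)$volume
  for (dt in c(0.01, 0.1, 1)) {
    c1 <- diffusion_step(conc, m, spec, dt)
    expect_equal(sum(c1) * vol, 30 * vol, tolerance = 1e-13)
  }
  for (i in 1:5000) conc <- diffusion_step(conc, m, spec, 1)
  expect_equal(conc, c(15, 15), tolerance = 1e-9)
  # uniform concentration unchanged
  expect_equal(diffusion_step(c(7, 7), m, spec, 1), c(7, 7))
})

test_that("diffusion matches the 1-D Gaussian kernel on a fine cylinder", {
  n <- 201; dx <- 1
  m <- morphology(data.frame(id = 1:n, parent = c(NA, 1:(n - 1)),
                             length = dx, diam = 1, region = "soma"))
  D <- 0.3
  conc <- rep(0, n); conc[101] <- 1 / dx  # unit amount point load
  spec <- diffusion_spec(D_Na = D)
  dt <- 0.25   # D dt / dx^2 = 0.075, comfortably stable
  t_end <- 50
  for (i in seq_len(t_end / dt)) conc <- diffusion_step(conc, m, spec, dt)
  x <- (seq_len(n) - 101) * dx
  exact <- exp(-x^2 / (4 * D * t_end)) / sqrt(4 * pi * D * t_end)
  rms <- sqrt(mean((conc - exact)^2)) / max(exact)
  expect_lt(rms, 0.02)
  expect_equal(sum(conc) * dx, 1, tolerance = 1e-12)  # conservation
})

test_that("steady-state pump current has the closed-form zero, saturation and shape", {
  spec <- default_na_pump()
  spec$density <- 5e-12
  Na_eq <- 150 * (spec$k2 * spec$k4 / (spec$k1 * spec$k3))^(1 / 3)
  expect_equal(pump_current_steady_state(Na_eq, 150, spec), 0,
               tolerance = 1e-18)
  # analytic saturation limit (F/3) rho k3
  sat <- (96485.33212 / 3) * 5e-12 * spec$k3 * 1e6
  expect_equal(pump_current_steady_state(1e9, 150, spec), sat,
               tolerance = 1e-4 * sat)
  # monotone non-decreasing, steeper at 30 than at 10 mM, one inflection
  na <- seq(0, 60, by = 0.5)
  cur <- pump_current_steady_state(na, 150, spec)
  expect_true(all(diff(cur) >= 0))
  slope <- diff(cur) / 0.5
  expect_gt(slope[na[-1] == 30], slope[na[-1] == 10])
  curvature_sign <- sign(diff(slope))
  expect_equal(sum(diff(curvature_sign[curvature_sign != 0]) != 0), 1L)
})

test_that("kinetic pump relaxes to the steady-state closed form", {
  spec <- default_na_pump()
  spec$density <- 1e-11
  for (Na_i in c(5, 10, 20, 40)) {
    # ODE-equilibrium oracle: integrate the occupancy ODE to equilibrium
    occ <- 0
    for (i in 1:5000) {
      res <- pump_current_kinetic(occ, Na_i, 150, spec, dt = 0.5,
                                  density = 1e-11)
      occ <- res$occupancy
    }
    ss <- pump_current_steady_state(Na_i, 150, spec, density = 1e-11)
    expect_equal(res$current, ss, tolerance = 1e-3)
    if (Na_i == 40) expect_lt(abs(res$current - ss) / abs(ss), 1e-3)
  }
  # step increase in Na_i: current relaxes monotonically to the new value
  occ <- pump_current_kinetic(0, 10, 150, spec, dt = 1e6)$occupancy
  cur <- numeric(120); o <- occ
  for (i in seq_along(cur)) {
    r <- pump_current_kinetic(o, 30, 150, spec, dt = 0.25)
    cur[i] <- r$current; o <- r$occupancy
  }
  expect_true(all(diff(cur) < 0))  # decays monotonically toward equilibrium
  expect_equal(cur[120], pump_current_steady_state(30, 150, spec),
               tolerance = 1e-6)
  # no pump, no current
  spec0 <- spec; spec0$density <- 0
  expect_equal(pump_current_kinetic(0, 30, 150, spec0, 0.1)$current, 0)
  expect_error(pump_current_kinetic(2e-11, 10, 150, spec, 0.1),
               "occupancy")
})

test_that("NCX current reverses at V = 3 E_Na - 2 E_Ca", {
  spec <- default_ncx(I_max = 0.05)
  cases <- expand.grid(Na_i = c(8, 15, 30), Ca_i = c(5e-5, 2e-4, 1e-3))
  for (i in seq_len(nrow(cases))) {
    Vr <- ncx_reversal(cases$Na_i[i], 150, cases$Ca_i[i], 2)
    at_rev <- ncx_current(cases$Na_i[i], 150, cases$Ca_i[i], 2, Vr, spec)
    scale <- abs(ncx_current(cases$Na_i[i], 150, cases$Ca_i[i], 2, Vr + 25,
                             spec))
    expect_lt(abs(at_rev) / scale, 1e-9)
    # reverse mode above, forward mode below
    expect_gt(ncx_current(cases$Na_i[i], 150, cases$Ca_i[i], 2, Vr + 5,
                          spec), 0)
    expect_lt(ncx_current(cases$Na_i[i], 150, cases$Ca_i[i], 2, Vr - 5,
                          spec), 0)
  }
  # the worked reversal point: Na_i 15, Ca_i 1e-4, 37 C -> about -80 mV
  expect_equal(ncx_reversal(15, 150, 1e-4, 2, 310.15), -80.1, tolerance = 0.1)
  spec0 <- default_ncx(I_max = 0)
  expect_equal(ncx_current(15, 150, 1e-4, 2, -60, spec0), 0)
  expect_error(ncx_current(0, 150, 1e-4, 2, -60, spec), "positive")
})

test_that("ca_balance_rate vanishes at the stable state and at buffer equilibrium", {
  ncx <- default_ncx(I_max = 0.05)
  cap <- default_ca_pump(); cap$density <- 2e-14
  buf <- default_buffer()
  geo <- segment_geometry(50, 1.2)
  for (nai in c(10, 20, 35)) {
    ca_ss <- stable_state_ca(nai, V = -70, ncx = ncx, ca_pump = cap)
    bound_eq <- buf$total_buffer * ca_ss / (buf$k_off / buf$k_on + ca_ss)
    r <- ca_balance_rate(ca_ss, nai, bound_eq, V = -70, ncx = ncx,
                         ca_pump = cap, buffer = buf,
                         area = geo$lateral_area, volume = geo$volume)
    scale <- abs(ca_balance_rate(2 * ca_ss, nai, bound_eq, V = -70,
                                 ncx = ncx, ca_pump = cap, buffer = buf,
                                 area = geo$lateral_area,
                                 volume = geo$volume))
    expect_lt(abs(r) / scale, 1e-8)
  }
  # buffer at equilibrium contributes nothing
  r_nobuf <- ca_balance_rate(1e-4, 20, 0, -70, ncx, cap, NULL,
                             geo$lateral_area, geo$volume)
  bound_eq <- buf$total_buffer * 1e-4 / (buf$k_off / buf$k_on + 1e-4)
  r_buf <- ca_balance_rate(1e-4, 20, bound_eq, -70, ncx, cap, buf,
                           geo$lateral_area, geo$volume)
  expect_equal(r_buf, r_nobuf, tolerance = 1e-12)
  # with no exchanger and closed channels the scalar ODE relaxes to the
  # pump-only equilibrium Ca_o k2 k4 / (k1 k3)
  ncx0 <- default_ncx(I_max = 0)
  ca <- 5e-4
  for (i in 1:400000) {
    ca <- ca + 0.05 * ca_balance_rate(ca, 10, 0, -70, ncx0, cap, NULL,
                                      geo$lateral_area, geo$volume)
  }
  eq <- 2 * cap$k2 * cap$k4 / (cap$k1 * cap$k3)
  expect_equal(ca, eq, tolerance = 1e-4)
})
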