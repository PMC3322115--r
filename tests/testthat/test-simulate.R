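test_that("a zero-contrast stimulus leaves the network at rest", {
  z <- drifting_grating(contrast = 0)
  rest <- resting_state(net_single)$potentials
  for (eng in c("ode45", "staged")) {
    sim <- simulate_network(net_single, z, 0.3, engine = eng)
    expect_lt(max(abs(sweep(sim$potentials, 2, rest))), 1e-6)
  }
})

test_that("both engines match the analytic oracle at low contrast", {
  sfs <- c(0.2, 0.49, 1)
  thetas <- c(0, 0.6)
  for (sf in sfs) for (th in thetas) for (s in c(1, -1)) {
    g <- drifting_grating(contrast = 0.01, spatial_frequency = sf,
                          orientation = th, drift_sign = s)
    z <- analytic_linear_response(net_single, g)[net_single$central]
    sim <- simulate_network(net_single, g, 1.5, engine = "staged")
    fc <- fourier_components(
      sim$potentials[, state_index(net_single, "cortex1", "central")],
      sim$times, 2)
    expect_lt(abs(fc$f1_amplitude - Mod(z)) / Mod(z), 0.005)
  }
  # one adaptive-integrator case against the same oracle
  g <- drifting_grating(contrast = 0.01, spatial_frequency = 0.49)
  z <- analytic_linear_response(net_single, g)[net_single$central]
  sim <- simulate_network(net_single, g, 1.5, engine = "ode45")
  fc <- fourier_components(
    sim$potentials[, state_index(net_single, "cortex1", "central")],
    sim$times, 2)
  expect_lt(abs(fc$f1_amplitude - Mod(z)) / Mod(z), 0.005)
  # oracle phase is also reproduced
  expect_equal(fc$f1_phase, Arg(z), tolerance = 0.01)
})

test_that("the staged and adaptive engines agree on the full network", {
  g <- drifting_grating(contrast = 0.25, spatial_frequency = 0.49)
  net <- build_network(cal_params, cortical_stages = 3, grid_spacing = 0.5)
  s1 <- simulate_network(net, g, 0.8, engine = "ode45")
  s2 <- simulate_network(net, g, 0.8, engine = "staged")
  expect_lt(max(abs(s1$potentials - s2$potentials)), 0.01)
  sp <- spot_stimulus(x = 0.2)
  s1 <- simulate_network(net, sp, 0.2, engine = "ode45")
  s2 <- simulate_network(net, sp, 0.2, engine = "staged")
  expect_lt(max(abs(s1$potentials - s2$potentials)), 0.01)
})

test_that("rates are the rectified potentials, with graded cells masked", {
  sp <- spot_stimulus(x = 0.2)
  sim <- simulate_network(net_single, sp, 0.15, engine = "staged")
  spiking <- setdiff(seq_len(ncol(sim$rates)),
                     net_single$idx$sub[rep(c(TRUE, TRUE, FALSE, FALSE),
                                            net_single$m)])
  expect_equal(sim$rates[, spiking],
               rectify(sim$potentials[, spiking],
                       cal_params$g_rect))
  graded <- net_single$idx$sub[c(1, 2, 5, 6)]
  expect_true(all(is.na(sim$rates[, graded])))
})

test_that("temporal phase shifts translate the response without distortion", {
  base <- drifting_grating(contrast = 0.01, spatial_frequency = 0.49)
  shifted <- drifting_grating(contrast = 0.01, spatial_frequency = 0.49,
                              phase = pi / 3)
  j <- state_index(net_single, "cortex1", "central")
  f <- function(st) {
    sim <- simulate_network(net_single, st, 1.5, engine = "staged")
    fourier_components(sim$potentials[, j], sim$times, 2)
  }
  f1 <- f(base); f2 <- f(shifted)
  expect_lt(abs(f1$f1_amplitude - f2$f1_amplitude) / f1$f1_amplitude, 0.005)
  dphi <- (f1$f1_phase - f2$f1_phase) %% (2 * pi)
  expect_equal(dphi, pi / 3, tolerance = 0.01)
})

test_that("reported metrics are stable under grid refinement", {
  g <- drifting_grating(contrast = 0.3, spatial_frequency = 0.49)
  j <- state_index(net_single, "cortex1", "central")
  f1 <- vapply(c(0.001, 0.0005), function(h) {
    sim <- simulate_network(net_single, g, 1.5, dt = h, engine = "staged")
    fourier_components(sim$rates[, j], sim$times, 2)$f1_amplitude
  }, numeric(1))
  expect_lt(abs(diff(f1)) / f1[1], 0.001)
})

test_that("Fourier analysis satisfies its closed-form identities", {
  tt <- seq(0, 3, by = 0.001)
  # pure sinusoid
  fc <- fourier_components(2.5 * sin(2 * pi * 2 * tt), tt, 2)
  expect_equal(fc$f0, 0, tolerance = 1e-10)
  expect_equal(fc$f1_amplitude, 2.5, tolerance = 1e-6)
  expect_equal(fc$f1_phase, 0, tolerance = 1e-6)
  # half-wave rectified sinusoid: F0 = A/pi, F1 = A/2, ratio pi/2
  hw <- fourier_components(pmax(3 * sin(2 * pi * 2 * tt), 0), tt, 2)
  expect_equal(hw$f0, 3 / pi, tolerance = 1e-3)
  expect_equal(hw$f1_amplitude, 3 / 2, tolerance = 1e-3)
  expect_equal(hw$f1_amplitude / hw$f0, pi / 2, tolerance = 1e-3)
  # constant trace has no fundamental
  expect_equal(fourier_components(rep(4, length(tt)), tt, 2)$f1_amplitude,
               0, tolerance = 1e-9)
  # too-short traces are rejected
  expect_error(fourier_components(sin(tt[tt < 1]), tt[tt < 1], 2),
               "analysis error")
})

test_that("simulation inputs are validated", {
  expect_error(simulate_network(net_single, drifting_grating(), -1))
  expect_error(simulate_network(net_single, drifting_grating(), 1,
                                initial = c(1, 2)))
})
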