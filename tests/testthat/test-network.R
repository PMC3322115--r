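test_that("the generator function is a threshold-linear rectifier", {
  expect_equal(rectify(-5, 7.2), 0)
  expect_equal(rectify(1, 7.2), 7.2)
  expect_equal(rectify(1.944, 7.2), 14, tolerance = 1e-3)
  expect_equal(rectify(c(-1, 0, 2), 7.2), c(0, 0, 14.4))
})

test_that("channel layouts alternate signs and use the stated spacings", {
  lay <- channel_layout(tbl_params)
  expect_equal(nrow(lay), 2)
  expect_equal(sort(lay$sign), c(-1, 1))
  expect_equal(abs(diff(lay$x)), tbl_params$opposite_sign_spacing)
  expect_equal(lay$tau[lay$sign == 1], 11)   # on channel is the slower one
  expect_equal(lay$tau[lay$sign == -1], 9)
  lay6 <- channel_layout(model_parameters(m = 6))
  expect_equal(nrow(lay6), 6)
  expect_equal(sum(lay6$sign == 1), 3)
  expect_equal(sort(unique(lay6$y)), c(-0.75, 0, 0.75))
  expect_equal(abs(unique(lay6$x))[1], 0.05)
})

test_that("difference-of-Gaussians pooling honours the gain normalisation", {
  p <- model_parameters(surround_enabled = TRUE)
  lay <- channel_layout(p)
  # a spot much larger than the surround approximates a full-field stimulus
  ff <- spot_stimulus(contrast = 1, side = 40, onset = 0, duration = 1)
  on_drive <- dog_drive(ff, lay[1, ], 0.5, p)
  expect_equal(on_drive, p$g_cen - p$g_sur, tolerance = 1e-6)  # 14 mV
  # zero contrast gives zero drive
  z <- drifting_grating(contrast = 0)
  expect_equal(dog_drive(z, lay[1, ], 0.1, p), 0)
  # off-channel drive mirrors the on-channel drive for a grating
  g <- drifting_grating(spatial_frequency = 0.49)
  lay_off_at_on <- lay[2, ]
  lay_off_at_on$x <- lay[1, "x"]
  expect_equal(dog_drive(g, lay_off_at_on, seq(0, 0.4, by = 0.05), p),
               -dog_drive(g, lay[1, ], seq(0, 0.4, by = 0.05), p))
})

test_that("sign symmetry: inverted polarity with swapped channel signs matches", {
  p <- model_parameters()
  lay <- channel_layout(p)
  sp_light <- spot_stimulus(contrast = 1, x = 0.2)
  sp_dark <- spot_stimulus(contrast = -1, x = -0.2)
  on_ch <- lay[1, ]                   # at +x, sign +1
  off_ch <- lay[2, ]                  # at -x, sign -1
  expect_equal(dog_drive(sp_light, on_ch, 0.01, p),
               dog_drive(sp_dark, off_ch, 0.01, p))
})

test_that("closed-form pooling agrees with pixel-grid quadrature", {
  p <- model_parameters(surround_enabled = TRUE)
  lay <- channel_layout(p)
  stims <- list(spot_stimulus(x = 0.2, y = -0.1),
                bar_stimulus(x = -0.3, orientation = 0.35),
                drifting_grating(spatial_frequency = 0.7,
                                 orientation = 0.3),
                contrast_reversing_grating(spatial_phase = 0.6))
  for (st in stims) {
    a <- dog_drive(st, lay[1, ], 0.015, p)
    b <- dog_drive_numeric(st, lay[1, ], 0.015, p)
    expect_lt(abs(a - b) / max(abs(a), 1e-9), 1e-3)
  }
})

test_that("network weights follow the architecture", {
  net <- net_full3
  expect_equal(ncol(net$stages$cortex1$W), net$m)
  # intracortical rows renormalised to the intracortical gain
  expect_equal(rowSums(net$stages$cortex2$W),
               rep(cal_params$g_cort, nrow(net$stages$cortex2$W)))
  expect_equal(rowSums(net$stages$cortex3$W),
               rep(cal_params$g_cort, nrow(net$stages$cortex3$W)))
  # geniculocortical weights are Gaussian in distance
  pos <- net$stages$cortex1$pos
  lay <- net$layout
  w_expect <- cal_params$g_GC *
    exp(-((pos[5, 1] - lay$x[1])^2 + (pos[5, 2] - lay$y[1])^2) /
          cal_params$r_cort^2)
  expect_equal(net$stages$cortex1$W[5, 1], w_expect)
})

test_that("resting state matches its closed form and the published rates", {
  rs <- resting_state(net_full3)
  relay_idx <- state_index(net_full3, "relay")
  expect_equal(unname(rs$rates[relay_idx]), rep(14, 2), tolerance = 1e-6)
  # stage-1 cortical cells are hyperpolarised: no spontaneous rate
  expect_true(all(rs$rates[state_index(net_full3, "cortex1")] == 0))
  expect_true(all(rs$potentials[state_index(net_full3, "cortex1")] < 0))
  # later stages rest depolarised
  expect_true(all(rs$rates[state_index(net_full3, "cortex2")] > 0))
  expect_true(all(rs$rates[state_index(net_full3, "cortex3")] >
                    rs$rates[state_index(net_full3, "cortex2")]))
  # the rest state is a fixed point of both right-hand sides
  zstim <- drifting_grating(contrast = 0)
  dsub <- subcortical_rhs(rs$potentials[net_full3$idx$sub], zstim, 0.1,
                          net_full3)
  expect_equal(max(abs(dsub)), 0, tolerance = 1e-9)
  dcort <- cortical_rhs(rs$potentials, 0.1, net_full3)
  expect_equal(max(abs(dcort)), 0, tolerance = 1e-9)
})

test_that("sub-cortical stages form a delayed low-pass cascade", {
  sp <- spot_stimulus(contrast = 1, side = 0.38, x = 0.05, duration = 0.04)
  sim <- simulate_network(net_single, sp, 0.25, engine = "staged")
  on_cols <- net_single$idx$sub[1:4]
  peaks <- apply(sim$potentials[, on_cols], 2,
                 function(z) sim$times[which.max(z)])
  expect_true(all(diff(peaks) > 0))   # each stage peaks after its driver
  # off-channel leads: its relay response peaks before the on relay
  dk <- spot_stimulus(contrast = -1, side = 0.38, x = -0.05,
                      duration = 0.04)
  sim_d <- simulate_network(net_single, dk, 0.25, engine = "staged")
  t_on <- sim$times[which.max(sim$potentials[, net_single$idx$sub[4]])]
  t_off <- sim_d$times[which.max(sim_d$potentials[, net_single$idx$sub[8]])]
  expect_lt(t_off, t_on)
})

test_that("dark stimuli dominate light stimuli at mirror positions", {
  j <- state_index(net_single, "cortex1", "central")
  run <- function(contrast, x) {
    b <- bar_stimulus(contrast = contrast, width = 0.25, x = x,
                      duration = 0.04)
    sim <- simulate_network(net_single, b, 0.25, engine = "staged")
    max(sim$potentials[, j])
  }
  expect_gt(run(-1, -0.2), run(1, 0.2))
  expect_gt(run(-1, -0.3), run(1, 0.3))
})

test_that("paired channels approximate a spatial derivative", {
  expect_lt(spatial_profile_and_derivative_check(0.1, 0.4), 0.05)
  # the approximation sharpens as the separation shrinks ...
  e_small <- spatial_profile_and_derivative_check(0.01, 0.4)
  e_mid <- spatial_profile_and_derivative_check(0.1, 0.4)
  e_large <- spatial_profile_and_derivative_check(0.8, 0.4)
  expect_lt(e_small, e_mid)
  expect_lt(e_mid, e_large)
  expect_gt(e_large, 0.2)            # two radii apart: clearly not a derivative
})

test_that("on/off impulse-response difference approximates a tau derivative", {
  expect_lt(temporal_profile_and_derivative_check(11, 9), 0.05)
  expect_equal(temporal_profile_and_derivative_check(10, 10), 0)
  expect_gt(temporal_profile_and_derivative_check(12, 8),
            temporal_profile_and_derivative_check(11, 9))
})
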