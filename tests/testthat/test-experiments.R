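test_that("the activity criterion is a 5 Hz elevation threshold", {
  expect_false(is_active(4.9))
  expect_true(is_active(5.0))
  expect_true(is_active(12))
  expect_false(is_active(0))        # resting-rate-only neuron
})

test_that("half-width extraction handles peaks, wrap-around and flat curves", {
  x <- seq(0, 350, by = 10)
  y <- pmax(0, 20 * cos((x - 40) * pi / 180))  # peak at 40, half at +-60
  expect_equal(half_width_at_half_height(x, y), 60, tolerance = 2)
  # peak near the wrap-around point
  y2 <- pmax(0, 20 * cos((x - 350) * pi / 180))
  expect_equal(half_width_at_half_height(x, y2), 60, tolerance = 2)
  expect_true(is.na(half_width_at_half_height(x, rep(0, length(x)))))
  expect_true(is.na(half_width_at_half_height(x, rep(3, length(x)))))
})

test_that("spatial-frequency tuning peaks near the half-cycle resonance", {
  sw <- spatial_frequency_tuning(
    net_single, spatial_frequencies = exp(seq(log(0.1), log(2),
                                              length.out = 36)))
  expect_equal(sw$optimum, 0.49, tolerance = 0.1)
  expect_true(sw$active[1])
  # brute-force check of the analytic optimum against a fine grid search
  sfs <- seq(0.05, 1.5, by = 0.005)
  amp <- vapply(sfs, function(sf)
    Mod(analytic_linear_response(
      net_single, drifting_grating(contrast = 1, spatial_frequency = sf))),
    numeric(1))
  expect_equal(optimal_spatial_frequency_analytic(net_single),
               sfs[which.max(amp)], tolerance = 0.005)
})

test_that("the surround narrows spatial-frequency bandwidth", {
  sfs <- exp(seq(log(0.1), log(2), length.out = 36))
  no_sur <- spatial_frequency_tuning(net_single,
                                     spatial_frequencies = sfs)
  p_sur <- calibrated_parameters(surround_enabled = TRUE)
  net_sur <- build_network(p_sur, cortical_stages = 1, single_cell = TRUE)
  with_sur <- spatial_frequency_tuning(net_sur, spatial_frequencies = sfs)
  expect_lt(with_sur$bandwidths[1], no_sur$bandwidths[1])
})

test_that("direction selectivity arises from the on/off latency difference", {
  ds <- direction_selectivity(net_single)
  expect_true(ds$active[1])
  # the default model is strongly selective
  expect_gt(ds$index_ratio_form[1], 0.9)
  expect_gt(ds$index_normalised_form[1], 0.8)
  # iceberg effect: spike-rate selectivity exceeds potential selectivity
  expect_gt(ds$index_normalised_form[1],
            ds$index_potential_normalised_form[1])
  expect_gt(ds$index_ratio_form[1], ds$index_potential_ratio_form[1])
  # with equal time constants the indices collapse to zero
  p0 <- cal_params
  p0$tau_on <- 10; p0$tau_off <- 10
  net0 <- build_network(p0, cortical_stages = 1, single_cell = TRUE)
  ds0 <- direction_selectivity(net0)
  expect_equal(ds0$index_normalised_form[1], 0, tolerance = 1e-6)
  expect_equal(ds0$index_ratio_form[1], 0, tolerance = 1e-6)
})

test_that("direction index grows monotonically with the latency difference", {
  mc <- run_multi_column_dsi(cal_params, n_columns = 5,
                             delta_tau_range = c(0, 2))
  expect_equal(mc$delta_tau, seq(0, 2, length.out = 5))
  expect_true(all(diff(mc$index_normalised_form) > -1e-9))
  expect_equal(mc$index_normalised_form[1], 0, tolerance = 1e-6)
  # the pooled population reaches into lower index bins than the
  # single maximal-difference column
  expect_lt(min(mc$index_normalised_form), 0.2)
  expect_gt(max(mc$index_normalised_form), 0.8)
  # seeded random draws are reproducible
  r1 <- run_multi_column_dsi(cal_params, n_columns = 3, random = TRUE,
                             seed = 7)
  r2 <- run_multi_column_dsi(cal_params, n_columns = 3, random = TRUE,
                             seed = 7)
  expect_identical(r1$delta_tau, r2$delta_tau)
})

test_that("receptive fields show separate on/off subfields at stage 1", {
  rf <- map_receptive_field(net_single, grid_n = 9, readout = "peak")
  expect_true(all(rf$light >= 0) && all(rf$dark >= 0))
  expect_lt(rf$overlap_index, 0.2)
  # light subfield sits on the on-channel side, dark on the off side
  wl <- which(rf$light == max(rf$light), arr.ind = TRUE)[1, ]
  wd <- which(rf$dark == max(rf$dark), arr.ind = TRUE)[1, ]
  expect_gt(rf$x[wl["row"]], 0)
  expect_lt(rf$x[wd["row"]], 0)
  expect_gt(max(rf$dark), max(rf$light))   # off-domination
  # polarity symmetry of the mapping protocol: inverting the spot
  # contrast swaps which channel drives the response
  expect_gt(max(rf$dark), 0)
})

test_that("later cortical stages do not separate subfields further", {
  net6 <- build_network(cal_params6, cortical_stages = 3,
                        grid_spacing = 0.5)
  rf1 <- map_receptive_field(net6, stage = "cortex1", spot_side = 0.8,
                             grid_n = 7, readout = "peak")
  rf3 <- map_receptive_field(net6, stage = "cortex3", spot_side = 0.8,
                             grid_n = 7, readout = "peak")
  expect_lt(rf1$overlap_index, 0.2)
  expect_gte(rf3$overlap_index, rf1$overlap_index)
})

test_that("the spatiotemporal field is tilted by the latency difference", {
  st <- map_spatiotemporal_rf(net_single6, n_locations = 12)
  expect_gt(st$tilt_ms_per_deg, 5)         # off side leads by tens of ms
  expect_gt(st$peak_dark, st$peak_light)   # off-domination again
  # control with equal time constants: no tilt
  p0 <- calibrated_parameters(m = 6)
  p0$tau_on <- 10; p0$tau_off <- 10
  net0 <- build_network(p0, cortical_stages = 1, single_cell = TRUE)
  st0 <- map_spatiotemporal_rf(net0, n_locations = 12)
  expect_lt(abs(st0$tilt_ms_per_deg), 1)
})

test_that("the phase scan shows no null and a monotone phase advance", {
  ps <- phase_scan(net_single)
  expect_true(all(ps$f1_amplitude > 0))
  # unwrap the temporal phase: it must advance monotonically (one full
  # turn per full spatial-phase sweep) as the grating is displaced
  # towards the on-centre input
  dphi <- diff(ps$f1_phase)
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_true(all(dphi < 0) || all(dphi > 0))
  expect_equal(abs(sum(dphi)), 2 * pi * 15 / 16, tolerance = 0.2)
  # a half-period spatial shift inverts the linear geniculate drive
  z0 <- analytic_linear_response(
    net_single, contrast_reversing_grating(spatial_phase = 0.4),
    stage = "relay")
  z1 <- analytic_linear_response(
    net_single, contrast_reversing_grating(spatial_phase = 0.4 + pi),
    stage = "relay")
  expect_equal(z1, -z0)
})

test_that("modulation ratios separate simple from complex-like stages", {
  mr <- modulation_ratio(net_full3)
  r1 <- mr$per_stage$cortex1$ratio
  r3 <- mr$per_stage$cortex3$ratio
  expect_gt(min(r1, na.rm = TRUE), 1)            # stage 1: simple
  expect_lt(stats::median(r3, na.rm = TRUE),
            stats::median(r1, na.rm = TRUE))
  expect_lt(stats::median(r3, na.rm = TRUE), 1.05)  # close to or below 1
  expect_true(any(mr$per_stage$cortex2$active))
})

test_that("sub-cortical rectification lowers modulation and varies by column", {
  mm <- run_multi_column_modulation(cal_params,
                                    spontaneous_rates = c(14, 70),
                                    grid_spacing = 0.5)
  # onset contrast: spontaneous rate over the modelled sensitivity
  expect_equal(mm$rectification_onset_contrast[1], 0.05, tolerance = 0.05)
  # the strongly rectified column is less modulated at stage 1 than the
  # nearly unrectified one
  r14 <- stats::median(mm$columns[[1]]$per_stage$cortex1$ratio, na.rm = TRUE)
  r70 <- stats::median(mm$columns[[2]]$per_stage$cortex1$ratio, na.rm = TRUE)
  expect_lt(r14, r70)
  # a spontaneous rate high enough to prevent rectification reproduces the
  # unrectified column
  p_hi <- cal_params
  p_hi$spontaneous_lgn_rate <- 70
  p_hi$p0_sub <- 70 / p_hi$g_rect
  net_lin <- build_network(p_hi, grid_spacing = 0.5)
  mr_lin <- modulation_ratio(net_lin)
  expect_equal(stats::median(mr_lin$per_stage$cortex1$ratio, na.rm = TRUE),
               r70, tolerance = 0.02)
  expect_error(run_multi_column_modulation(cal_params,
                                           spontaneous_rates = c(5)))
})

test_that("modelled geniculate sensitivity reflects surround antagonism", {
  s <- modelled_geniculate_sensitivity(tbl_params)
  expect_equal(s$sensitivity, 280, tolerance = 0.05)
  expect_equal(s$max_sensitivity, 62 * 7.2)
  expect_lt(s$sensitivity, s$max_sensitivity)
})

test_that("population statistics are robust to cortical grid density", {
  ot_a <- orientation_tuning(net_coarse,
                             directions_deg = seq(0, 350, by = 10))
  net_sparse <- build_network(cal_params, cortical_stages = 1,
                              grid_spacing = 0.5)
  ot_b <- orientation_tuning(net_sparse,
                             directions_deg = seq(0, 350, by = 10))
  expect_lt(abs(ot_a$median_half_width - ot_b$median_half_width), 10)
})
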