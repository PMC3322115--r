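test_that("retinal geometry chain reproduces the published quantities", {
  g <- derive_retinal_geometry(1275, 0.20, 0.49)
  expect_equal(g$x_cell_concentration, 51)
  expect_equal(signif(g$same_sign_spacing, 2), 0.2)
  expect_equal(g$opposite_sign_spacing, 0.097, tolerance = 0.01)
  expect_equal(signif(g$opposite_sign_spacing, 1), 0.1)

  # ratio 1 collapses the two spacings
  g1 <- derive_retinal_geometry(1275, 0.20, 1)
  expect_equal(g1$opposite_sign_spacing, g1$same_sign_spacing)

  expect_error(derive_retinal_geometry(-1, 0.2, 0.5), "positive")
  expect_error(derive_retinal_geometry(1275, 0.2, 1.5), "ratio")
})

test_that("patch cell counts follow concentration times area", {
  g <- derive_retinal_geometry(1275, 0.20, 0.49)
  expect_identical(count_patch_ganglion_cells(g, 2), 204L)
  expect_gt(count_patch_ganglion_cells(g, 2), 200)
  expect_identical(count_patch_ganglion_cells(51, 1), 51L)
  expect_identical(count_patch_ganglion_cells(51, 0.5), 13L)  # 12.75 rounds
  expect_error(count_patch_ganglion_cells(51, -1), "positive")
})

test_that("geometry derivation is covariant under magnification rescaling", {
  g1 <- derive_retinal_geometry(1275, 0.20, 0.49)
  g2 <- derive_retinal_geometry(1275, 0.40, 0.49)
  # cells/deg^2 scales with the square of mm/deg; spacings with its inverse
  expect_equal(g2$x_cell_concentration, 4 * g1$x_cell_concentration)
  expect_equal(g2$same_sign_spacing, g1$same_sign_spacing / 2)
  expect_equal(g2$opposite_sign_spacing, g1$opposite_sign_spacing / 2)
})

test_that("cortical linear density follows the published reduction chain", {
  expect_equal(cortical_linear_density(78440, 0.45, 0.794, 3),
               sqrt(78440 * 0.45 * 0.794 / 3))
  expect_equal(cortical_linear_density(78440, 0.45, 0.794, 3), 96.66,
               tolerance = 1e-3)
  expect_equal(cortical_linear_density(1, 1, 1, 1), 1)
  expect_equal(cortical_linear_density(100, 1, 1, 4), 5)
})

test_that("centre-gain calibration matches the tabulated sensitivity", {
  cal <- calibrate_centre_gain(620, 0.73, 7.2)
  expect_equal(cal$g_cen, 62, tolerance = 0.02)
  expect_equal(cal$max_rate_sensitivity, 450, tolerance = 0.02)
  # cancellation identity
  expect_equal(calibrate_centre_gain(7.2 * 3.5, 1, 7.2)$g_cen, 3.5)
})

test_that("geniculocortical gain calibration reproduces both variants", {
  expect_equal(calibrate_geniculocortical_gain(model_parameters()), 4.21,
               tolerance = 0.05)
  expect_equal(calibrate_geniculocortical_gain(model_parameters(m = 6)),
               1.47, tolerance = 0.05)
  expect_identical(calibrate_geniculocortical_gain(model_parameters(), 0), 0)
  # exact linearity in the target
  g1 <- calibrate_geniculocortical_gain(model_parameters(), 70)
  g2 <- calibrate_geniculocortical_gain(model_parameters(), 140)
  expect_equal(g2, 2 * g1)
})

test_that("static polarisations follow their physiological targets", {
  cal <- calibrate_static_polarisations(model_parameters())
  expect_equal(cal$p0_sub, 14 / 7.2)
  expect_equal(cal$p0_sub, 1.94, tolerance = 0.005)
  expect_equal(cal$p0_stage1, -25.5, tolerance = 0.005)
  expect_equal(calibrate_static_polarisations(
    model_parameters(), mean_spontaneous_rate_late = 0)$p0_late, 0)
  # rate-derived polarisations scale inversely with the generator gain
  c2 <- calibrate_static_polarisations(model_parameters(g_rect = 14.4))
  expect_equal(c2$p0_sub, cal$p0_sub / 2)
  expect_error(calibrate_static_polarisations(
    model_parameters(), resting_minus_threshold_stage1 = 1), "threshold")
})

test_that("defaults hold the tabulated values and invariants are enforced", {
  p <- model_parameters()
  expect_equal(p$g_cen, 62)
  expect_equal(p$g_sur, 48)
  expect_equal(p$g_rect, 7.2)
  expect_equal(p$g_GC, 4.21)
  expect_equal(model_parameters(m = 6)$g_GC, 1.47)
  expect_equal(c(p$r_cen, p$r_sur, p$r_cort), c(0.4, 1.1, 2.8))
  expect_equal(c(p$tau_on, p$tau_off, p$tau_cort), c(11, 9, 10))
  expect_equal(c(p$p0_sub, p$p0_stage1, p$p0_late), c(1.94, -25.5, 0.646))
  expect_error(model_parameters(r_sur = 0.3), "surround radius")
  expect_error(model_parameters(tau_off = 12), "tau_on")
  expect_error(model_parameters(p0_stage1 = 5), "hyperpolarising")
  expect_error(model_parameters(m = 4), "m must be")
})

test_that("full-precision calibration chain is self-consistent", {
  p <- calibrated_parameters()
  expect_equal(p$p0_sub, 14 / 7.2)
  expect_equal(p$p0_stage1, -25.5)
  # round-trip: chain values agree with tabulated ones to ~two figures
  expect_equal(p$g_GC, 4.21, tolerance = 0.05)
  net <- build_network(p, cortical_stages = 1, single_cell = TRUE)
  g <- drifting_grating(contrast = 1,
                        spatial_frequency =
                          optimal_spatial_frequency_analytic(net))
  amp <- Mod(analytic_linear_response(net, g)[net$central])
  expect_equal(amp, 70, tolerance = 1e-6)  # sensitivity target hit exactly
})

test_that("parameter files round-trip through YAML", {
  p <- model_parameters(m = 6, surround_enabled = TRUE)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(unclass(q), unclass(p))
  # bundled default file reproduces the default set
  expect_equal(unclass(read_parameters()), unclass(model_parameters()))
})
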