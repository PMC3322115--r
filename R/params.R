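#' Model parameters for the cortical column model
#'
#' Builds the complete parameter set of the feedforward column model. The
#' defaults are the published working values of the model: gains in
#' mV per contrast-unit, Gaussian radii in degrees of visual angle, time
#' constants in milliseconds, static polarisations in mV.
#'
#' The Gaussian spatial profile used throughout is `exp(-(d/r)^2)`, i.e. `r`
#' is the 1/e radius, the convention of the difference-of-Gaussians
#' receptive-field literature from which the radii are taken.
#'
#' @param g_cen Centre-mechanism contrast sensitivity, mV per contrast-unit.
#' @param g_sur Surround-mechanism contrast sensitivity, mV per contrast-unit.
#' @param g_rect Gain of the generator (potential-to-rate) function, Hz/mV.
#' @param g_cort Intracortical gain (dimensionless); each cortical neuron's
#'   input weights from the previous cortical stage sum to this value.
#' @param g_GC Geniculocortical gain (dimensionless). Default 4.21 for the
#'   two-channel model and 1.47 for the six-channel model.
#' @param r_cen,r_sur 1/e radii of the centre and surround Gaussians, deg.
#' @param r_cort 1/e radius of cortical convergence, deg.
#' @param tau_on,tau_off Time constants of the on- and off-centre sub-cortical
#'   channels, ms. The off channel is faster (`tau_off < tau_on`), which is
#'   the sole source of direction selectivity in the model.
#' @param tau_cort Time constant of cortical cells, ms.
#' @param p0_sub Sub-cortical static polarisation, mV; sets the spontaneous
#'   geniculate rate `g_rect * p0_sub`.
#' @param p0_stage1 Static polarisation of the first cortical stage at the
#'   patch centre, mV (hyperpolarising, hence negative).
#' @param p0_late Static polarisation of cortical stages 2 and 3, mV.
#' @param m Number of sub-cortical channels, 2 (basic) or 6 (elongated).
#' @param patch_side Side length of the modelled visual-field patch, deg.
#' @param cortical_grid_spacing Spacing of the cortical neuron grid, deg.
#' @param opposite_sign_spacing Distance between the on- and off-channel
#'   receptive-field centres, deg. Default 0.1, the nearest-neighbour
#'   distance between opposite-sign X-type ganglion cells at 11 deg
#'   eccentricity.
#' @param elongation_spacing Same-sign channel spacing along the long axis in
#'   the six-channel model, deg.
#' @param surround_enabled Include the antagonistic surround mechanism?
#'   The basic model omits it.
#' @param subcortical_rectification_enabled Rectify the ganglion-to-relay and
#'   relay-to-cortex signals? The basic model passes graded potentials.
#' @param spontaneous_lgn_rate Spontaneous impulse rate of geniculate relay
#'   cells, Hz.
#' @param resting_minus_threshold_stage1 Resting potential minus threshold for
#'   every first-stage cortical cell, mV (negative: these cells are
#'   hyperpolarised and have no spontaneous rate). If `NULL` it is derived
#'   from `p0_stage1` so that the static polarisation at the patch centre
#'   equals `p0_stage1`.
#' @return An object of class `v1_params` (a validated list).
#' @examples
#' p <- model_parameters()
#' p$g_cen
#' p6 <- model_parameters(m = 6)
#' p6$g_GC
#' @export
model_parameters <- function(g_cen = 62, g_sur = 48, g_rect = 7.2,
                             g_cort = 1, g_GC = NULL,
                             r_cen = 0.4, r_sur = 1.1, r_cort = 2.8,
                             tau_on = 11, tau_off = 9, tau_cort = 10,
                             p0_sub = 1.94, p0_stage1 = -25.5,
                             p0_late = 0.646,
                             m = 2, patch_side = 2,
                             cortical_grid_spacing = 0.1,
                             opposite_sign_spacing = 0.1,
                             elongation_spacing = 0.75,
                             surround_enabled = FALSE,
                             subcortical_rectification_enabled = FALSE,
                             spontaneous_lgn_rate = 14,
                             resting_minus_threshold_stage1 = NULL) {
  if (is.null(g_GC)) g_GC <- if (m == 6) 1.47 else 4.21
  p <- list(
    g_cen = g_cen, g_sur = g_sur, g_rect = g_rect, g_cort = g_cort,
    g_GC = g_GC, r_cen = r_cen, r_sur = r_sur, r_cort = r_cort,
    tau_on = tau_on, tau_off = tau_off, tau_cort = tau_cort,
    p0_sub = p0_sub, p0_stage1 = p0_stage1, p0_late = p0_late,
    m = as.integer(m), patch_side = patch_side,
    cortical_grid_spacing = cortical_grid_spacing,
    opposite_sign_spacing = opposite_sign_spacing,
    elongation_spacing = elongation_spacing,
    surround_enabled = isTRUE(surround_enabled),
    subcortical_rectification_enabled =
      isTRUE(subcortical_rectification_enabled),
    spontaneous_lgn_rate = spontaneous_lgn_rate,
    resting_minus_threshold_stage1 = resting_minus_threshold_stage1
  )
  class(p) <- "v1_params"
  validate_parameters(p)
  p
}

#' Full-precision calibrated parameter set
#'
#' Runs the model's calibration chain at full precision instead of using the
#' rounded tabulated values: the sub-cortical static polarisation is solved
#' from the 14 Hz spontaneous geniculate rate (14/7.2 mV), the
#' geniculocortical gain is solved so that the central first-stage cell's
#' grating contrast sensitivity is exactly 70 mV per contrast-unit, and the
#' first-stage static polarisation is anchored at its tabulated value at the
#' patch centre of the two-channel model, which fixes the resting distance
#' below threshold for every variant.
#'
#' The distinction matters only for responses that sit within a fraction of
#' a millivolt of threshold — notably the unit-contrast flashed spots and
#' bars used for receptive-field mapping, which cross threshold under the
#' full-precision chain but not under the rounded values. Grating
#' experiments are insensitive to it.
#'
#' @param m Number of sub-cortical channels (2 or 6).
#' @param target_sensitivity Cortical contrast sensitivity target,
#'   mV per contrast-unit.
#' @param ... Further arguments passed to [model_parameters()].
#' @return A `v1_params` object.
#' @examples
#' calibrated_parameters()$g_GC
#' @export
calibrated_parameters <- function(m = 2, target_sensitivity = 70, ...) {
  base <- model_parameters(m = m, ...)
  base$p0_sub <- base$spontaneous_lgn_rate / base$g_rect
  base$g_GC <- calibrate_geniculocortical_gain(base, target_sensitivity)
  # anchor: tabulated stage-1 static polarisation of the two-channel model
  ref <- if (m == 2) base else model_parameters(m = 2, ...)
  ref$p0_sub <- base$p0_sub
  if (m != 2)
    ref$g_GC <- calibrate_geniculocortical_gain(ref, target_sensitivity)
  lay2 <- channel_layout(ref)
  w2 <- ref$g_GC * exp(-((lay2$x^2 + lay2$y^2) / ref$r_cort^2))
  v_rmt <- ref$p0_stage1 + ref$p0_sub * sum(w2)
  base$resting_minus_threshold_stage1 <- v_rmt
  lay <- channel_layout(base)
  w <- base$g_GC * exp(-((lay$x^2 + lay$y^2) / base$r_cort^2))
  base$p0_stage1 <- v_rmt - base$p0_sub * sum(w)
  validate_parameters(base)
  base
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model parameters: positive radii
#' with `r_sur > r_cen`, `tau_on > tau_off > 0`, positive gains, a
#' hyperpolarising `p0_stage1`, a depolarising `p0_sub`, and a channel count
#' of 2 or 6.
#'
#' @param p A `v1_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "v1_params"))
  chk <- function(ok, msg) if (!ok) stop("invalid parameters: ", msg,
                                         call. = FALSE)
  chk(all(c(p$r_cen, p$r_sur, p$r_cort) > 0), "radii must be positive")
  chk(p$r_sur > p$r_cen, "surround radius must exceed centre radius")
  chk(p$tau_off > 0 && p$tau_on >= p$tau_off,
      "need tau_on >= tau_off > 0 (the off channel is never the slower one)")
  chk(p$tau_cort > 0, "tau_cort must be positive")
  chk(p$g_rect > 0, "g_rect must be positive")
  chk(p$g_cen > 0 && p$g_sur >= 0 && p$g_GC > 0 && p$g_cort >= 0,
      "gains must be positive")
  chk(p$p0_stage1 < 0, "p0_stage1 must be hyperpolarising (negative)")
  chk(p$p0_sub > 0, "p0_sub must be depolarising (positive)")
  chk(p$m %in% c(2L, 6L), "m must be 2 or 6")
  chk(p$patch_side > 0 && p$cortical_grid_spacing > 0,
      "patch geometry must be positive")
  chk(p$opposite_sign_spacing > 0, "channel spacing must be positive")
  chk(p$spontaneous_lgn_rate >= 0, "spontaneous rate must be non-negative")
  if (!is.null(p$resting_minus_threshold_stage1))
    chk(p$resting_minus_threshold_stage1 < 0,
        "stage-1 resting potential must lie below threshold")
  invisible(p)
}

#' Derive retinal geometry from published anatomical quantities
#'
#' Converts a beta-cell (X-type ganglion cell) areal concentration on the
#' retina into visual-degree units and derives the same-sign and
#' opposite-sign nearest-neighbour spacings, assuming a square array with
#' equal numbers of on- and off-centre cells.
#'
#' With the published primitives (1275 cells/mm^2 at 2.2 mm eccentricity,
#' 0.20 mm/deg, opposite/same-sign distance ratio 0.49) this gives
#' 51 cells/deg^2, a same-sign spacing of 0.198 deg (about 0.2 deg) and an
#' opposite-sign spacing of 0.097 deg (about 0.1 deg).
#'
#' @param beta_concentration Beta-cell concentration, cells/mm^2.
#' @param magnification Retinal magnification factor, mm/deg.
#' @param opposite_sign_ratio Ratio of opposite-sign to same-sign
#'   nearest-neighbour distance (dimensionless, < 1).
#' @param eccentricity Eccentricity of the modelled patch, deg.
#' @return A `v1_geometry` list with fields `beta_cell_concentration`,
#'   `retinal_magnification`, `x_cell_concentration` (cells/deg^2),
#'   `same_sign_spacing`, `opposite_sign_spacing` (deg), `eccentricity`.
#'   Values are kept at full precision; round only for reporting.
#' @examples
#' g <- derive_retinal_geometry(1275, 0.20, 0.49)
#' round(g$x_cell_concentration)      # 51 cells/deg^2
#' signif(g$same_sign_spacing, 2)     # 0.2 deg
#' signif(g$opposite_sign_spacing, 2) # 0.097 deg, printed as 0.1 deg
#' @export
derive_retinal_geometry <- function(beta_concentration, magnification,
                                    opposite_sign_ratio, eccentricity = 11) {
  if (!all(c(beta_concentration, magnification, opposite_sign_ratio) > 0))
    stop("invalid parameters: all geometry inputs must be positive",
         call. = FALSE)
  if (opposite_sign_ratio > 1)
    stop("invalid parameters: opposite_sign_ratio must be <= 1",
         call. = FALSE)
  conc <- beta_concentration * magnification^2        # cells/deg^2
  same <- 1 / sqrt(conc / 2)                          # square array, half on
  opp <- opposite_sign_ratio * same
  out <- list(beta_cell_concentration = beta_concentration,
              retinal_magnification = magnification,
              x_cell_concentration = conc,
              same_sign_spacing = same,
              opposite_sign_spacing = opp,
              eccentricity = eccentricity)
  class(out) <- "v1_geometry"
  out
}

#' Count X-type ganglion cells in the modelled patch
#'
#' @param geometry A `v1_geometry` object, or directly an areal concentration
#'   in cells/deg^2.
#' @param patch_side Side of the square visual-field patch, deg.
#' @return Integer cell count (concentration x area, rounded to nearest).
#' @examples
#' count_patch_ganglion_cells(51, 2)  # 204 cells in the 2x2 deg patch
#' @export
count_patch_ganglion_cells <- function(geometry, patch_side = 2) {
  conc <- if (inherits(geometry, "v1_geometry"))
    geometry$x_cell_concentration else as.numeric(geometry)
  if (!is.finite(conc) || conc <= 0 || patch_side <= 0)
    stop("invalid parameters: concentration and patch side must be positive",
         call. = FALSE)
  as.integer(round(conc * patch_side^2))
}

#' Linear density of excitatory cortical neurons per stage
#'
#' Converts an areal cortical neuron density to a per-stage linear density:
#' multiply by the cortical magnification factor to express it per square
#' degree, keep only the excitatory fraction, divide among the processing
#' stages, and take the square root for a square array.
#'
#' @param areal_density Neurons per mm^2 of cortex.
#' @param cortical_magnification Cortical magnification, mm^2/deg^2.
#' @param excitatory_fraction Fraction of neurons that are excitatory.
#' @param n_stages Number of cortical stages sharing the population.
#' @return Linear density, cells/deg.
#' @examples
#' cortical_linear_density(78440, 0.45, 0.794, 3)  # ~96.6 cells/deg
#' @export
cortical_linear_density <- function(areal_density, cortical_magnification,
                                    excitatory_fraction, n_stages = 3) {
  if (!all(c(areal_density, cortical_magnification,
             excitatory_fraction) > 0) || n_stages < 1)
    stop("invalid parameters: densities and fractions must be positive",
         call. = FALSE)
  sqrt(areal_density * cortical_magnification * excitatory_fraction /
         n_stages)
}

#' Calibrate the centre-mechanism contrast sensitivity
#'
#' The centre Gaussian is normalised so that its full two-dimensional
#' integral of sensitivity equals `g_cen`; the uniform-field response of the
#' centre mechanism to unit contrast is therefore `g_cen` mV. `g_cen` is set
#' from the retinal centre-mechanism rate sensitivity, attenuated across the
#' retino-geniculate synapse and converted from Hz to mV through the
#' generator gain.
#'
#' @param retinal_sensitivity Retinal centre-mechanism contrast sensitivity,
#'   Hz per contrast-unit.
#' @param attenuation Retina-to-geniculate transmission factor
#'   (dimensionless).
#' @param g_rect Generator-function gain, Hz/mV.
#' @return List with `g_cen` (mV per contrast-unit) and
#'   `max_rate_sensitivity` (`g_cen * g_rect`, Hz per contrast-unit), the
#'   implied maximum geniculate rate sensitivity.
#' @examples
#' cal <- calibrate_centre_gain(620, 0.73, 7.2)
#' signif(cal$g_cen, 2)                # 63, tabulated as 62
#' signif(cal$max_rate_sensitivity, 2) # ~450 Hz per contrast-unit
#' @export
calibrate_centre_gain <- function(retinal_sensitivity = 620,
                                  attenuation = 0.73, g_rect = 7.2) {
  if (!all(c(retinal_sensitivity, attenuation, g_rect) > 0))
    stop("invalid parameters: calibration inputs must be positive",
         call. = FALSE)
  g_cen <- retinal_sensitivity * attenuation / g_rect
  list(g_cen = g_cen, max_rate_sensitivity = g_cen * g_rect)
}

#' Calibrate the geniculocortical gain
#'
#' Finds the geniculocortical gain for which the membrane-potential response
#' of the central first-stage cortical cell to a drifting grating at the
#' optimal orientation and spatial frequency equals a target contrast
#' sensitivity (mV per contrast-unit). Because the dynamics up to the
#' first-stage potential are linear in the gain, a single analytic response
#' at a reference gain is computed and rescaled.
#'
#' @param params A `v1_params` object (its `g_GC` is ignored).
#' @param target_sensitivity Target potential amplitude per unit contrast for
#'   the central first-stage cell, mV per contrast-unit.
#' @return The calibrated dimensionless gain.
#' @examples
#' round(calibrate_geniculocortical_gain(model_parameters()), 2)
#' @export
calibrate_geniculocortical_gain <- function(params,
                                            target_sensitivity = 70) {
  validate_parameters(params)
  if (target_sensitivity < 0)
    stop("invalid parameters: target sensitivity must be >= 0", call. = FALSE)
  if (target_sensitivity == 0) return(0)
  ref <- params
  ref$g_GC <- 1
  net <- build_network(ref, cortical_stages = 1, single_cell = TRUE)
  sf_opt <- optimal_spatial_frequency_analytic(net)
  g <- drifting_grating(contrast = 1, spatial_frequency = sf_opt,
                        orientation = 0, drift_sign = 1)
  amp <- Mod(analytic_linear_response(net, g, stage = "cortex1"))
  if (!is.finite(amp) || amp <= 0)
    stop("calibration error: zero reference response", call. = FALSE)
  target_sensitivity / amp
}

#' Calibrate the static polarisations
#'
#' Sets the three static-polarisation parameters from physiological targets:
#' `p0_sub` so that the sub-cortical resting rate equals the spontaneous
#' geniculate rate; `p0_stage1` so that the resting potential of the central
#' first-stage cortical cell sits a prescribed distance below threshold given
#' the resting geniculate drive; and `p0_late` so that the mean of the
#' stage-2 and stage-3 cortical spontaneous rates equals a target.
#'
#' @param params A `v1_params` object supplying gains, geometry and the
#'   spontaneous geniculate rate.
#' @param resting_minus_threshold_stage1 Target resting potential minus
#'   threshold for first-stage cortical cells, mV (must be negative).
#' @param mean_spontaneous_rate_late Target mean spontaneous rate of the two
#'   later cortical stages, Hz.
#' @return List with `p0_sub`, `p0_stage1` (value at the patch centre) and
#'   `p0_late`, all in mV.
#' @examples
#' calibrate_static_polarisations(model_parameters())
#' @export
calibrate_static_polarisations <- function(params,
                                           resting_minus_threshold_stage1 =
                                             -9.17,
                                           mean_spontaneous_rate_late = 3.1) {
  validate_parameters(params)
  if (resting_minus_threshold_stage1 >= 0)
    stop("calibration error: stage-1 resting potential must be below ",
         "threshold", call. = FALSE)
  if (mean_spontaneous_rate_late < 0)
    stop("calibration error: spontaneous rate must be >= 0", call. = FALSE)
  p0_sub <- params$spontaneous_lgn_rate / params$g_rect
  lay <- channel_layout(params)
  w <- params$g_GC *
    exp(-((lay$x^2 + lay$y^2) / params$r_cort^2))
  p0_stage1 <- resting_minus_threshold_stage1 - sum(w) * p0_sub
  # resting stage-2 rate = g_rect * p0_late, stage-3 = 2 * g_rect * p0_late
  p0_late <- 2 * mean_spontaneous_rate_late / (3 * params$g_rect)
  list(p0_sub = p0_sub, p0_stage1 = p0_stage1, p0_late = p0_late)
}

#' Write parameters to a YAML file
#'
#' @param params A `v1_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  x <- unclass(params)
  x$resting_minus_threshold_stage1 <-
    if (is.null(x$resting_minus_threshold_stage1)) "derived"
    else x$resting_minus_threshold_stage1
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read parameters from a YAML file
#'
#' Reads a parameter file written by [write_parameters()] (or the bundled
#' default file) and re-validates every invariant.
#'
#' @param path File path; default is the bundled file with the published
#'   parameter values.
#' @return A `v1_params` object.
#' @export
read_parameters <- function(path = system.file("extdata",
                                               "default_parameters.yaml",
                                               package = "v1column")) {
  x <- yaml::read_yaml(path)
  if (identical(x$resting_minus_threshold_stage1, "derived"))
    x$resting_minus_threshold_stage1 <- NULL
  do.call(model_parameters, x)
}

#' @export
print.v1_params <- function(x, ...) {
  cat("Column-model parameters (", x$m, " sub-cortical channels)\n",
      sep = "")
  cat(sprintf("  gains: g_cen %.3g, g_sur %.3g, g_rect %.3g Hz/mV, g_GC %.3g, g_cort %.3g\n",
              x$g_cen, x$g_sur, x$g_rect, x$g_GC, x$g_cort))
  cat(sprintf("  radii (deg): centre %.3g, surround %.3g, cortical %.3g\n",
              x$r_cen, x$r_sur, x$r_cort))
  cat(sprintf("  time constants (ms): on %.3g, off %.3g, cortical %.3g\n",
              x$tau_on, x$tau_off, x$tau_cort))
  cat(sprintf("  static polarisations (mV): sub %.3g, stage1 %.3g, late %.3g\n",
              x$p0_sub, x$p0_stage1, x$p0_late))
  cat(sprintf("  surround %s, sub-cortical rectification %s\n",
              if (x$surround_enabled) "on" else "off",
              if (x$subcortical_rectification_enabled) "on" else "off"))
  invisible(x)
}
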