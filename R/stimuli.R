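#' Stimuli
#'
#' All stimuli are local-contrast fields c(x, y, t): the difference between
#' local and background luminance divided by background luminance. Gratings
#' are defined on the whole plane; spots and bars are rectangular regions of
#' uniform contrast presented for a finite duration.
#'
#' @name stimuli
NULL

new_stimulus <- function(kind, fields) {
  s <- c(list(kind = kind), fields)
  class(s) <- "v1_stimulus"
  s
}

#' Drifting sinusoidal grating
#'
#' Contrast field `c * sin(omega_s * u - drift_sign * omega_t * t + phase)`
#' with `u = x cos(theta) + y sin(theta)`. `theta` is the axis of spatial
#' variation (the bars run perpendicular to it). With the default channel
#' layout (off-centre channel at negative x, on-centre at positive x),
#' `drift_sign = +1` moves the grating from the off-channel towards the
#' on-channel, which is the preferred direction of the model.
#'
#' @param contrast Michelson contrast (dimensionless).
#' @param spatial_frequency Cycles/deg.
#' @param orientation Axis of spatial variation, radians.
#' @param temporal_frequency Drift rate, Hz (default 2).
#' @param phase Spatial phase, radians.
#' @param drift_sign +1 or -1, drift direction along the orientation axis.
#' @return A `v1_stimulus` object.
#' @export
drifting_grating <- function(contrast = 0.3, spatial_frequency = 0.49,
                             orientation = 0, temporal_frequency = 2,
                             phase = 0, drift_sign = 1) {
  stopifnot(spatial_frequency >= 0, temporal_frequency > 0,
            drift_sign %in% c(-1, 1))
  new_stimulus("drifting_grating", list(
    contrast = contrast,
    spatial_frequency = spatial_frequency,
    omega_s = 2 * pi * spatial_frequency,
    theta = orientation,
    temporal_frequency = temporal_frequency,
    omega_t = 2 * pi * temporal_frequency,
    phase = phase, drift_sign = drift_sign))
}

#' Stationary contrast-reversing grating
#'
#' Contrast field `c * sin(omega_s * u + phase) * sin(omega_t * t)`: a
#' standing grating whose contrast reverses sinusoidally in time. Its
#' space-time profile is separable, unlike the drifting grating.
#'
#' @inheritParams drifting_grating
#' @param spatial_phase Spatial phase of the standing pattern, radians.
#' @return A `v1_stimulus` object.
#' @export
contrast_reversing_grating <- function(contrast = 1, spatial_frequency = 0.49,
                                       orientation = 0,
                                       temporal_frequency = 2,
                                       spatial_phase = 0) {
  stopifnot(spatial_frequency >= 0, temporal_frequency > 0)
  new_stimulus("contrast_reversing_grating", list(
    contrast = contrast,
    spatial_frequency = spatial_frequency,
    omega_s = 2 * pi * spatial_frequency,
    theta = orientation,
    temporal_frequency = temporal_frequency,
    omega_t = 2 * pi * temporal_frequency,
    phase = spatial_phase))
}

#' Flashed square spot
#'
#' A square of uniform contrast (+1 for light, -1 for dark), flashed for a
#' finite duration. Axis-aligned.
#'
#' @param contrast Local contrast; magnitude at most 1.
#' @param side Side length, deg.
#' @param x,y Centre position, deg.
#' @param onset Stimulus onset, s.
#' @param duration Presentation time, s.
#' @return A `v1_stimulus` object.
#' @export
spot_stimulus <- function(contrast = 1, side = 0.38, x = 0, y = 0,
                          onset = 0, duration = 0.04) {
  stopifnot(abs(contrast) <= 1, side > 0, duration > 0, onset >= 0)
  new_stimulus("spot", list(
    contrast = contrast, width = side, height = side, side = side,
    x = x, y = y, theta = 0, onset = onset, duration = duration))
}

#' Flashed bar
#'
#' A rectangle of uniform contrast flashed for a finite duration. `width` is
#' measured along the orientation axis `theta` (the narrow dimension for an
#' "optimally oriented" bar), `length` along the perpendicular.
#'
#' @param contrast Local contrast; +1 light, -1 dark.
#' @param width Bar width, deg.
#' @param length Bar length, deg (default spans well beyond the 2-deg patch).
#' @param x,y Centre position, deg.
#' @param orientation Axis of the bar's narrow dimension, radians; 0 gives a
#'   bar elongated along y.
#' @param onset Stimulus onset, s.
#' @param duration Presentation time, s.
#' @return A `v1_stimulus` object.
#' @export
bar_stimulus <- function(contrast = 1, width = 0.25, length = 4,
                         x = 0, y = 0, orientation = 0,
                         onset = 0, duration = 0.04) {
  stopifnot(abs(contrast) <= 1, width > 0, length > 0, duration > 0,
            onset >= 0)
  new_stimulus("bar", list(
    contrast = contrast, width = width, height = length,
    x = x, y = y, theta = orientation, onset = onset, duration = duration))
}

#' Evaluate a stimulus contrast field
#'
#' Returns the local contrast c(x, y, t). The stimulus is defined on the
#' whole plane, so positions outside the modelled patch are legal.
#' Arguments are recycled to a common length.
#'
#' @param stimulus A `v1_stimulus`.
#' @param x,y Positions, deg.
#' @param t Times, s.
#' @return Numeric vector of contrasts.
#' @examples
#' g <- drifting_grating()
#' evaluate_contrast(g, 0.2, 0, 0.1)
#' @export
evaluate_contrast <- function(stimulus, x, y, t) {
  stopifnot(inherits(stimulus, "v1_stimulus"))
  n <- max(length(x), length(y), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  s <- stimulus
  switch(
    s$kind,
    drifting_grating =
      s$contrast * sin(s$omega_s * (x * cos(s$theta) + y * sin(s$theta)) -
                         s$drift_sign * s$omega_t * t + s$phase),
    contrast_reversing_grating =
      s$contrast * sin(s$omega_s * (x * cos(s$theta) + y * sin(s$theta)) +
                         s$phase) * sin(s$omega_t * t),
    {
      u <- (x - s$x) * cos(s$theta) + (y - s$y) * sin(s$theta)
      v <- -(x - s$x) * sin(s$theta) + (y - s$y) * cos(s$theta)
      inside <- abs(u) <= s$width / 2 & abs(v) <= s$height / 2 &
        t >= s$onset & t < s$onset + s$duration
      s$contrast * as.numeric(inside)
    })
}

#' Breakpoints of a stimulus time course
#'
#' Times at which the contrast field is discontinuous in time (onset and
#' offset of flashed stimuli). The integrator splits its time span at these
#' points. Gratings have none.
#'
#' @param stimulus A `v1_stimulus`.
#' @return Numeric vector of times, s (possibly empty).
#' @export
stimulus_breakpoints <- function(stimulus) {
  if (stimulus$kind %in% c("spot", "bar"))
    c(stimulus$onset, stimulus$onset + stimulus$duration)
  else numeric(0)
}

#' Standard stimulus ensembles for the in-silico experiments
#'
#' Returns the stimulus list used by each experiment, matching the published
#' protocols: receptive-field maps use flashed +-1-contrast squares of side
#' 0.38 deg (0.8 deg for the six-channel variant) and 40 ms duration on a
#' grid of locations; the spatiotemporal map uses +-1 bars 0.25 deg wide at
#' 16 evenly spaced locations; orientation tuning uses drifting gratings at
#' 0.49 cycles/deg, 2 Hz, contrast 0.3; the phase scan uses unit-contrast
#' contrast-reversing gratings over a spatial-phase sweep; the modulation
#' experiment uses a drifting grating of contrast 0.25.
#'
#' @param experiment One of `"rf_map"`, `"rf_map_6ch"`, `"orientation"`,
#'   `"sf_tuning"`, `"dsi"`, `"strf"`, `"phase_scan"`, `"modulation"`.
#' @param patch_side Patch side length, deg.
#' @param grid_n Locations per axis for the receptive-field map grid.
#' @return List of `v1_stimulus` objects.
#' @export
make_standard_stimuli <- function(experiment, patch_side = 2, grid_n = 16) {
  half <- patch_side / 2
  grid_pos <- function(n) seq(-half, half, length.out = n)
  sq_grid <- function(side) {
    xs <- grid_pos(grid_n)
    out <- list()
    for (cc in c(1, -1)) for (yy in xs) for (xx in xs)
      out[[length(out) + 1L]] <-
        spot_stimulus(contrast = cc, side = side, x = xx, y = yy,
                      duration = 0.04)
    out
  }
  switch(
    experiment,
    rf_map = sq_grid(0.38),
    rf_map_6ch = sq_grid(0.8),
    orientation = lapply(seq(0, 355, by = 5) * pi / 180, function(th)
      drifting_grating(contrast = 0.3, spatial_frequency = 0.49,
                       orientation = th)),
    sf_tuning = lapply(exp(seq(log(0.1), log(2),
                               length.out = ceiling(16 * log2(20)) + 1)),
                       function(sf)
                         drifting_grating(contrast = 0.3,
                                          spatial_frequency = sf)),
    dsi = lapply(c(1, -1), function(s)
      drifting_grating(contrast = 0.3, spatial_frequency = 0.49,
                       drift_sign = s)),
    strf = {
      xs <- grid_pos(16)
      out <- list()
      for (cc in c(1, -1)) for (xx in xs)
        out[[length(out) + 1L]] <-
          bar_stimulus(contrast = cc, width = 0.25, x = xx, duration = 0.04)
      out
    },
    phase_scan = lapply(seq(0, 337.5, by = 22.5) * pi / 180, function(ph)
      contrast_reversing_grating(contrast = 1, spatial_phase = ph)),
    modulation = list(drifting_grating(contrast = 0.25,
                                       spatial_frequency = 0.49)),
    stop("unknown experiment name: ", experiment, call. = FALSE)
  )
}

#' @export
print.v1_stimulus <- function(x, ...) {
  cat("Stimulus:", x$kind, "\n")
  flds <- setdiff(names(x), "kind")
  vals <- vapply(flds, function(f) format(x[[f]], digits = 4), "")
  cat(paste0("  ", flds, " = ", vals, collapse = "\n"), "\n")
  invisible(x)
}
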