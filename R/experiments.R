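# In-silico experiments: receptive-field maps, tuning curves, direction
# selectivity, phase scans, modulation ratios, multi-column populations.

# Fourier summary of every column of a response matrix (time x neuron).
fourier_matrix <- function(x, times, frequency, discard_cycles = 1) {
  period <- 1 / frequency
  t0 <- times[1] + discard_cycles * period
  n_cycles <- floor((times[length(times)] - t0) / period + 1e-9)
  if (n_cycles < 2)
    stop("analysis error: trace covers fewer than 2 cycles after the ",
         "transient", call. = FALSE)
  keep <- times >= t0 - 1e-12 & times < t0 + n_cycles * period - 1e-12
  x <- x[keep, , drop = FALSE]
  tt <- times[keep]
  w <- 2 * pi * frequency
  f0 <- colMeans(x)
  a <- 2 * colMeans(x * sin(w * tt))
  b <- 2 * colMeans(x * cos(w * tt))
  list(f0 = f0, f1 = sqrt(a^2 + b^2), phase = atan2(b, a),
       n_cycles = n_cycles)
}

#' Activity criterion for population statistics
#'
#' A neuron enters the population statistics only if the optimal drifting
#' grating elevates its mean impulse rate by at least the criterion level
#' (5 Hz), mimicking the experimenter's decision to pass over unresponsive
#' cells.
#'
#' @param elevation Mean-rate elevation over the resting rate, Hz.
#' @param criterion Threshold, Hz.
#' @return Logical vector.
#' @examples
#' is_active(c(4.9, 5, 12))
#' @export
is_active <- function(elevation, criterion = 5) {
  elevation >= criterion
}

#' Half-width at half-height of a tuning curve
#'
#' Centres the curve on its peak (circularly, for orientation sweeps) and
#' finds the half-height crossings on each side by linear interpolation.
#'
#' @param x Abscissa values (deg for orientation sweeps).
#' @param y Responses (baseline zero).
#' @param circular Treat the abscissa as circular with the given period.
#' @param period Circular period (360 for direction sweeps).
#' @return Half-width in abscissa units ((right - left)/2), or `NA` if the
#'   curve does not cross half-height on both sides.
#' @export
half_width_at_half_height <- function(x, y, circular = TRUE, period = 360) {
  if (all(!is.finite(y)) || max(y, na.rm = TRUE) <= 0) return(NA_real_)
  pk <- which.max(y)
  half <- y[pk] / 2
  if (circular) {
    sh <- ((x - x[pk] + period / 2) %% period) - period / 2
    o <- order(sh)
    sh <- sh[o]; yy <- y[o]
  } else {
    sh <- x - x[pk]; yy <- y
  }
  cross <- function(side) {
    idx <- if (side > 0) which(sh >= 0) else rev(which(sh <= 0))
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      if ((yy[i] - half) * (yy[j] - half) <= 0 && yy[i] != yy[j])
        return(sh[i] + (half - yy[i]) * (sh[j] - sh[i]) / (yy[j] - yy[i]))
    }
    NA_real_
  }
  hw <- (cross(+1) - cross(-1)) / 2
  hw
}

# Shared sweep driver: simulate a list of gratings and summarise every
# neuron of a stage. Returns elevation (F0 minus rest), F1 of rate, and F1
# of potential, each [stimulus x neuron].
run_grating_sweep <- function(network, stimuli, stage = "cortex1",
                              duration = 1.5, dt = 0.001,
                              engine = "staged", discard_cycles = 1) {
  cols <- state_index(network, stage)
  rest <- resting_state(network)
  rest_rate <- rectify(rest$potentials[cols], network$params$g_rect)
  n <- length(cols)
  elev <- f1r <- f1p <- matrix(NA_real_, length(stimuli), n)
  for (k in seq_along(stimuli)) {
    sim <- simulate_network(network, stimuli[[k]], duration, dt = dt,
                            engine = engine)
    fr <- fourier_matrix(sim$rates[, cols, drop = FALSE], sim$times,
                         stimuli[[k]]$temporal_frequency, discard_cycles)
    fp <- fourier_matrix(sim$potentials[, cols, drop = FALSE], sim$times,
                         stimuli[[k]]$temporal_frequency, discard_cycles)
    elev[k, ] <- fr$f0 - rest_rate
    f1r[k, ] <- fr$f1
    f1p[k, ] <- fp$f1
  }
  list(elevation = elev, f1_rate = f1r, f1_potential = f1p,
       rest_rate = rest_rate)
}

#' Analytic optimum spatial frequency of the central stage-1 cell
#'
#' Maximises the magnitude of the closed-form fundamental potential response
#' of the central first-stage cortical cell over grating spatial frequency,
#' at the preferred orientation and drift direction.
#'
#' @param network A `v1_network`.
#' @param interval Search interval, cycles/deg.
#' @return Optimal spatial frequency, cycles/deg.
#' @export
optimal_spatial_frequency_analytic <- function(network,
                                               interval = c(0.02, 2)) {
  f <- function(sf) {
    g <- drifting_grating(contrast = 1, spatial_frequency = sf,
                          orientation = 0, drift_sign = 1)
    -Mod(analytic_linear_response(network, g,
                                  stage = "cortex1")[network$central])
  }
  stats::optimize(f, interval = interval, tol = 1e-5)$minimum
}

#' Orientation tuning and its population histogram
#'
#' Drifts gratings of fixed spatial frequency and contrast across the patch
#' over a sweep of directions, measuring the elevation of each neuron's
#' mean impulse rate. Returns per-neuron tuning curves, the half-width at
#' half-height for every neuron passing the activity criterion, and the
#' central cell's curve.
#'
#' @param network A `v1_network`.
#' @param stage Cortical stage to analyse.
#' @param directions_deg Drift directions, deg (sweep of the orientation
#'   axis; bars run perpendicular).
#' @param spatial_frequency Cycles/deg (the population optimum).
#' @param contrast Grating contrast.
#' @param temporal_frequency Hz.
#' @param criterion Activity criterion, Hz.
#' @param engine,dt,duration Passed to [simulate_network()].
#' @return A list of class `v1_tuning` with elements `abscissa` (deg),
#'   `curves` (direction x neuron elevations, Hz), `central_curve`,
#'   `half_widths` (deg, `NA` for inactive or flat cells), `active`,
#'   `median_half_width`.
#' @export
orientation_tuning <- function(network, stage = "cortex1",
                               directions_deg = seq(0, 355, by = 5),
                               spatial_frequency = 0.49, contrast = 0.3,
                               temporal_frequency = 2, criterion = 5,
                               engine = "staged", dt = 0.001,
                               duration = 1.5) {
  stim <- lapply(directions_deg * pi / 180, function(th)
    drifting_grating(contrast = contrast,
                     spatial_frequency = spatial_frequency,
                     orientation = th,
                     temporal_frequency = temporal_frequency))
  sw <- run_grating_sweep(network, stim, stage, duration, dt, engine)
  n <- ncol(sw$elevation)
  peak_elev <- apply(sw$elevation, 2L, max)
  active <- is_active(peak_elev, criterion)
  hw <- rep(NA_real_, n)
  for (j in which(active))
    hw[j] <- half_width_at_half_height(directions_deg, sw$elevation[, j])
  out <- list(metric = "orientation half-width", abscissa = directions_deg,
              curves = sw$elevation,
              central_curve = sw$elevation[, network$central],
              half_widths = hw, active = active,
              median_half_width = stats::median(hw[active], na.rm = TRUE))
  class(out) <- "v1_tuning"
  out
}

#' Spatial-frequency tuning and its population histogram
#'
#' Drifts optimally oriented gratings over a logarithmic spatial-frequency
#' sweep and measures the elevation of mean rate. The optimum is the argmax
#' refined by a parabolic fit through the three surrounding samples;
#' bandwidth is the full width at half-height in octaves.
#'
#' @inheritParams orientation_tuning
#' @param spatial_frequencies Sweep values, cycles/deg (default 0.1-2 at 16
#'   points per octave).
#' @param orientation Optimal orientation, radians.
#' @return A list of class `v1_tuning` with `abscissa`, `curves`,
#'   `central_curve`, `optimum` (cycles/deg, central cell), `bandwidths`
#'   (octaves per active neuron, `NA` when the curve does not cross
#'   half-height on both sides), `active`.
#' @export
spatial_frequency_tuning <- function(network, stage = "cortex1",
                                     spatial_frequencies =
                                       exp(seq(log(0.1), log(2),
                                               length.out = 70)),
                                     orientation = 0, contrast = 0.3,
                                     temporal_frequency = 2, criterion = 5,
                                     engine = "staged", dt = 0.001,
                                     duration = 1.5) {
  stim <- lapply(spatial_frequencies, function(sf)
    drifting_grating(contrast = contrast, spatial_frequency = sf,
                     orientation = orientation,
                     temporal_frequency = temporal_frequency))
  sw <- run_grating_sweep(network, stim, stage, duration, dt, engine)
  n <- ncol(sw$elevation)
  active <- is_active(apply(sw$elevation, 2L, max), criterion)
  optimum <- function(y) {
    i <- which.max(y)
    if (i == 1L || i == length(y)) return(spatial_frequencies[i])
    xs <- spatial_frequencies[(i - 1L):(i + 1L)]
    ys <- y[(i - 1L):(i + 1L)]
    d <- (ys[1] - 2 * ys[2] + ys[3])
    if (d >= 0) return(xs[2])
    xs[2] - 0.5 * (xs[3] - xs[1]) / 2 * (ys[3] - ys[1]) / d
  }
  bandwidth <- function(y) {
    i <- which.max(y)
    half <- y[i] / 2
    lx <- log2(spatial_frequencies)
    crossing <- function(idx) {
      for (k in seq_len(length(idx) - 1L)) {
        a <- idx[k]; b <- idx[k + 1L]
        if ((y[a] - half) * (y[b] - half) <= 0 && y[a] != y[b])
          return(lx[a] + (half - y[a]) * (lx[b] - lx[a]) / (y[b] - y[a]))
      }
      NA_real_
    }
    hi <- crossing(i:length(y))
    lo <- crossing(i:1)
    hi - lo
  }
  bw <- rep(NA_real_, n)
  for (j in which(active)) bw[j] <- bandwidth(sw$elevation[, j])
  out <- list(metric = "spatial-frequency bandwidth",
              abscissa = spatial_frequencies,
              curves = sw$elevation, f1_rate = sw$f1_rate,
              central_curve = sw$elevation[, network$central],
              optimum = optimum(sw$elevation[, network$central]),
              bandwidths = bw, active = active,
              median_bandwidth = stats::median(bw[active], na.rm = TRUE))
  class(out) <- "v1_tuning"
  out
}

#' Direction selectivity indices
#'
#' Drifts the optimal grating in both directions and compares fundamental
#' Fourier amplitudes of the generator potential (intracellular convention)
#' and of the impulse rate (extracellular convention). Two index forms are
#' reported for each measure: `1 - a_anti / a_pref` and
#' `(a_pref - a_anti) / (a_pref + a_anti)`.
#'
#' @inheritParams orientation_tuning
#' @param spatial_frequency Cycles/deg; if `NULL`, the analytic optimum of
#'   the central cell is used.
#' @param orientation Radians.
#' @return A list with per-neuron vectors `a_pref`, `a_anti` (for rate and
#'   potential), `index_ratio_form`, `index_normalised_form` (rate),
#'   `index_potential_*` (potential), and `active`.
#' @export
direction_selectivity <- function(network, stage = "cortex1",
                                  orientation = 0, spatial_frequency = NULL,
                                  contrast = 0.3, temporal_frequency = 2,
                                  criterion = 5, engine = "staged",
                                  dt = 0.001, duration = 1.5) {
  if (is.null(spatial_frequency))
    spatial_frequency <- optimal_spatial_frequency_analytic(network)
  stim <- lapply(c(1, -1), function(s)
    drifting_grating(contrast = contrast,
                     spatial_frequency = spatial_frequency,
                     orientation = orientation, drift_sign = s,
                     temporal_frequency = temporal_frequency))
  sw <- run_grating_sweep(network, stim, stage, duration, dt, engine)
  pref <- pmax(sw$f1_rate[1L, ], sw$f1_rate[2L, ])
  anti <- pmin(sw$f1_rate[1L, ], sw$f1_rate[2L, ])
  # use the rate-preferred direction for the potential comparison too
  pref_dir <- ifelse(sw$f1_rate[1L, ] >= sw$f1_rate[2L, ], 1L, 2L)
  ppref <- ifelse(pref_dir == 1L, sw$f1_potential[1L, ],
                  sw$f1_potential[2L, ])
  panti <- ifelse(pref_dir == 1L, sw$f1_potential[2L, ],
                  sw$f1_potential[1L, ])
  idx <- function(a, b) {
    out <- cbind(ratio = 1 - b / a, normalised = (a - b) / (a + b))
    out[a <= 0, ] <- NA_real_
    out
  }
  ir <- idx(pref, anti)
  ip <- idx(ppref, panti)
  active <- is_active(apply(sw$elevation, 2L, max), criterion)
  list(spatial_frequency = spatial_frequency,
       a_pref = pref, a_anti = anti,
       a_pref_potential = ppref, a_anti_potential = panti,
       index_ratio_form = unname(ir[, "ratio"]),
       index_normalised_form = unname(ir[, "normalised"]),
       index_potential_ratio_form = unname(ip[, "ratio"]),
       index_potential_normalised_form = unname(ip[, "normalised"]),
       active = active)
}

#' Multi-column direction-selectivity population
#'
#' Rebuilds the basic model once per cortical column with a different
#' on/off time-constant difference and pools the direction indices. The
#' default is ten columns with differences equally spaced over 0-2 ms
#' (reproducible); uniform random draws are available behind a seed.
#'
#' @param params A `v1_params` for the template column.
#' @param n_columns Number of columns.
#' @param delta_tau_range Range of `tau_on - tau_off`, ms.
#' @param random Draw differences uniformly at random instead of equally
#'   spaced.
#' @param seed Seed for the random draws.
#' @param single_cell Analyse the central cell of each column only
#'   (default), or the full cortical grid.
#' @param ... Passed to [direction_selectivity()].
#' @return A list with `delta_tau` (ms) and pooled per-neuron index vectors
#'   (normalised and ratio forms), plus the per-column results.
#' @export
run_multi_column_dsi <- function(params, n_columns = 10,
                                 delta_tau_range = c(0, 2),
                                 random = FALSE, seed = NULL,
                                 single_cell = TRUE, ...) {
  stopifnot(n_columns >= 1, all(delta_tau_range >= 0))
  deltas <- if (random) {
    if (!is.null(seed)) set.seed(seed)
    sort(stats::runif(n_columns, delta_tau_range[1], delta_tau_range[2]))
  } else seq(delta_tau_range[1], delta_tau_range[2],
             length.out = n_columns)
  tau_mid <- (params$tau_on + params$tau_off) / 2
  cols <- lapply(deltas, function(d) {
    p <- params
    p$tau_on <- tau_mid + d / 2
    p$tau_off <- tau_mid - d / 2
    net <- build_network(p, cortical_stages = 1, single_cell = single_cell)
    direction_selectivity(net, ...)
  })
  list(delta_tau = deltas,
       index_normalised_form =
         unlist(lapply(cols, `[[`, "index_normalised_form")),
       index_ratio_form = unlist(lapply(cols, `[[`, "index_ratio_form")),
       active = unlist(lapply(cols, `[[`, "active")),
       columns = cols)
}

#' Receptive-field map from flashed spots
#'
#' Presents light and dark squares independently at each node of a location
#' grid and reads the neuron's impulse rate at a fixed delay after onset
#' (85 ms, the latency of the peak spot response). The subfield-overlap
#' index is `sum(min(L, D)) / sum(max(L, D))` over locations: near 0 for
#' separate on/off subfields (simple cells), larger when the subfields
#' overlap (complex-like cells).
#'
#' @param network A `v1_network`.
#' @param stage Cortical stage of the mapped neuron.
#' @param neuron Neuron index within the stage (default the central cell).
#' @param spot_side Spot side, deg (0.38 basic; 0.8 for the six-channel
#'   variant).
#' @param grid_n Locations per axis.
#' @param readout_time Delay from onset at which rate is read, s (the
#'   latency of the peak light-spot response).
#' @param readout `"fixed"` reads the rate elevation at `readout_time`;
#'   `"peak"` reads the peak elevation over the trace. Because off-centre
#'   responses lead on-centre responses by tens of milliseconds, a single
#'   fixed delay matched to the light response largely misses the dark
#'   response; the peak readout renders both subfields.
#' @param spot_duration Presentation time, s.
#' @param engine,dt Passed to [simulate_network()].
#' @return A list of class `v1_rfmap` with `x`, `y`, `light`, `dark`
#'   (rate-elevation matrices, Hz, clipped at zero) and `overlap_index`.
#' @export
map_receptive_field <- function(network, stage = "cortex1", neuron = NULL,
                                spot_side = 0.38, grid_n = 16,
                                readout_time = 0.085,
                                readout = c("fixed", "peak"),
                                spot_duration = 0.04,
                                engine = "staged", dt = 0.001) {
  readout <- match.arg(readout)
  cols <- state_index(network, stage)
  j <- cols[if (is.null(neuron)) network$central else neuron]
  rest_rate <- rectify(resting_state(network)$potentials[j],
                       network$params$g_rect)
  half <- network$params$patch_side / 2
  xs <- seq(-half, half, length.out = grid_n)
  dur <- if (readout == "fixed") readout_time else 2.5 * readout_time
  resp <- function(contrast) {
    m <- matrix(0, grid_n, grid_n)
    for (iy in seq_len(grid_n)) for (ix in seq_len(grid_n)) {
      st <- spot_stimulus(contrast = contrast, side = spot_side,
                          x = xs[ix], y = xs[iy],
                          duration = spot_duration)
      sim <- simulate_network(network, st, duration = dur,
                              dt = dt, engine = engine)
      r <- sim$rates[, j] - rest_rate
      m[ix, iy] <- max(0, if (readout == "fixed") r[length(r)] else max(r))
    }
    m
  }
  light <- resp(1)
  dark <- resp(-1)
  denom <- sum(pmax(light, dark))
  out <- list(x = xs, y = xs, light = light, dark = dark,
              overlap_index = if (denom > 0)
                sum(pmin(light, dark)) / denom else NA_real_)
  class(out) <- "v1_rfmap"
  out
}

#' Spatiotemporal receptive field from flashed bars
#'
#' Presents optimally oriented light and dark bars at locations across the
#' patch and maps the central neuron's rate against bar position and time.
#' The signed field is the light-minus-dark response; direction-selective
#' cells show contours tilted in space-time. The tilt metric is the slope
#' of the peak-response time against bar position (weighted by peak
#' magnitude), in ms/deg: 0 for a non-selective cell, positive when
#' off-side responses lead under the default layout (off channels on the
#' negative-x side).
#'
#' @param network A `v1_network` (six-channel variant recommended: it gives
#'   elongated contours).
#' @param stage,neuron Mapped neuron (default central first-stage cell).
#' @param n_locations Bar positions across the patch.
#' @param bar_width Bar width, deg.
#' @param bar_duration Presentation time, s.
#' @param record Recorded span, s.
#' @param engine,dt Passed to [simulate_network()].
#' @return A list of class `v1_strf` with `positions` (deg), `times` (s),
#'   `light`, `dark`, `field` (light minus dark, Hz), `tilt_ms_per_deg` and
#'   `peak_light`, `peak_dark` (Hz).
#' @export
map_spatiotemporal_rf <- function(network, stage = "cortex1", neuron = NULL,
                                  n_locations = 16, bar_width = 0.25,
                                  bar_duration = 0.04, record = 0.25,
                                  engine = "staged", dt = 0.001) {
  cols <- state_index(network, stage)
  j <- cols[if (is.null(neuron)) network$central else neuron]
  half <- network$params$patch_side / 2
  xs <- seq(-half, half, length.out = n_locations)
  run <- function(contrast, x0) {
    st <- bar_stimulus(contrast = contrast, width = bar_width, x = x0,
                       duration = bar_duration)
    sim <- simulate_network(network, st, duration = record, dt = dt,
                            engine = engine)
    sim$rates[, j]
  }
  nt <- length(seq(0, record, by = dt))
  light <- dark <- matrix(0, nt, n_locations)
  for (k in seq_len(n_locations)) {
    light[, k] <- run(1, xs[k])
    dark[, k] <- run(-1, xs[k])
  }
  times <- seq(0, record, by = dt)
  field <- light - dark
  peak_t <- peak_w <- rep(NA_real_, n_locations)
  for (k in seq_len(n_locations)) {
    i <- which.max(abs(field[, k]))
    peak_t[k] <- times[i]
    peak_w[k] <- abs(field[i, k])
  }
  use <- peak_w > 0.05 * max(peak_w)
  tilt <- if (sum(use) >= 3) {
    fit <- stats::lm(pt ~ x, data = data.frame(pt = peak_t[use] * 1000,
                                               x = xs[use]),
                     weights = peak_w[use])
    unname(stats::coef(fit)[2])
  } else NA_real_
  out <- list(positions = xs, times = times, light = light, dark = dark,
              field = field, tilt_ms_per_deg = tilt,
              peak_light = max(light), peak_dark = max(dark))
  class(out) <- "v1_strf"
  out
}

#' Response to a contrast-reversing grating stepped across the field
#'
#' A stationary grating whose contrast reverses sinusoidally is presented at
#' a sweep of spatial phases; the fundamental Fourier amplitude and
#' temporal phase of the central first-stage cell's impulse rate are
#' reported. A direction-selective cell shows no null (the amplitude stays
#' positive at every spatial phase) and its temporal phase advances as the
#' grating is displaced towards the on-centre input. The closed-form
#' geniculate phasors and their weighted sum are included to document the
#' two-vector account of the phase advance.
#'
#' @inheritParams orientation_tuning
#' @param spatial_phases_deg Spatial phases of the standing grating, deg.
#' @param spatial_frequency Cycles/deg; `NULL` for the analytic optimum.
#' @param orientation Radians.
#' @return A list of class `v1_phase_scan` with `spatial_phase_deg`,
#'   `f1_amplitude` (Hz), `f1_phase` (rad), `relay_vectors` (complex,
#'   channel x phase) and `drive_vector` (their weighted sum).
#' @export
phase_scan <- function(network, spatial_phases_deg = seq(0, 337.5,
                                                         by = 22.5),
                       spatial_frequency = NULL, orientation = 0,
                       contrast = 1, temporal_frequency = 2,
                       engine = "staged", dt = 0.001, duration = 1.5) {
  if (is.null(spatial_frequency))
    spatial_frequency <- optimal_spatial_frequency_analytic(network)
  j <- state_index(network, "cortex1", "central")
  amp <- ph <- numeric(length(spatial_phases_deg))
  relay <- matrix(0i, network$m, length(spatial_phases_deg))
  drive <- complex(length(spatial_phases_deg))
  for (k in seq_along(spatial_phases_deg)) {
    st <- contrast_reversing_grating(contrast = contrast,
                                     spatial_frequency = spatial_frequency,
                                     orientation = orientation,
                                     temporal_frequency = temporal_frequency,
                                     spatial_phase =
                                       spatial_phases_deg[k] * pi / 180)
    sim <- simulate_network(network, st, duration, dt = dt, engine = engine)
    fc <- fourier_components(sim$rates[, j], sim$times, temporal_frequency)
    amp[k] <- fc$f1_amplitude
    ph[k] <- fc$f1_phase
    z <- analytic_linear_response(network, st, stage = "relay")
    relay[, k] <- z
    drive[k] <- sum(network$stages$cortex1$W[network$central, ] * z)
  }
  out <- list(spatial_phase_deg = spatial_phases_deg,
              spatial_frequency = spatial_frequency,
              f1_amplitude = amp, f1_phase = ph,
              relay_vectors = relay, drive_vector = drive)
  class(out) <- "v1_phase_scan"
  out
}

#' Modulation ratio (F1/F0) across the cortical stages
#'
#' Drifts the optimal grating across the patch and computes, for every
#' active neuron in the requested cortical stages, the ratio of the
#' fundamental Fourier amplitude of the impulse rate to its mean. Simple
#' cells have ratios above 1; complex-like cells close to or below 1.
#'
#' @inheritParams orientation_tuning
#' @param spatial_frequency Cycles/deg; `NULL` for the analytic optimum.
#' @param stages Cortical stages to pool.
#' @param contrast Grating contrast (0.25, the published protocol).
#' @return A list of class `v1_modulation` with per-stage `ratios`
#'   (`NA` for inactive cells or zero mean rate), pooled `ratio` vector,
#'   `stage` labels and `active` flags.
#' @export
modulation_ratio <- function(network, stages = names(network$stages),
                             spatial_frequency = NULL, orientation = 0,
                             contrast = 0.25, temporal_frequency = 2,
                             criterion = 5, engine = "staged", dt = 0.001,
                             duration = 1.5) {
  if (is.null(spatial_frequency))
    spatial_frequency <- optimal_spatial_frequency_analytic(network)
  st <- drifting_grating(contrast = contrast,
                         spatial_frequency = spatial_frequency,
                         orientation = orientation,
                         temporal_frequency = temporal_frequency)
  sim <- simulate_network(network, st, duration, dt = dt, engine = engine)
  rest <- resting_state(network)
  res <- list()
  for (s in stages) {
    cols <- state_index(network, s)
    fr <- fourier_matrix(sim$rates[, cols, drop = FALSE], sim$times,
                         temporal_frequency)
    rest_rate <- rectify(rest$potentials[cols], network$params$g_rect)
    act <- is_active(fr$f0 - rest_rate, criterion)
    ratio <- ifelse(act & fr$f0 > 0, fr$f1 / fr$f0, NA_real_)
    res[[s]] <- list(ratio = ratio, active = act, f0 = fr$f0, f1 = fr$f1)
  }
  out <- list(per_stage = res,
              ratio = unlist(lapply(res, `[[`, "ratio")),
              stage = rep(stages, vapply(res, function(r)
                length(r$ratio), integer(1))),
              active = unlist(lapply(res, `[[`, "active")),
              spatial_frequency = spatial_frequency)
  class(out) <- "v1_modulation"
  out
}

#' Multi-column modulation-ratio population
#'
#' Re-runs the model with sub-cortical rectification enabled, once per
#' column, varying the spontaneous geniculate rate from its baseline up to
#' a level that prevents rectification, and pools the modulation ratios.
#' Each column's rectification-onset contrast (spontaneous rate divided by
#' the modelled geniculate sensitivity at the optimal spatial frequency) is
#' reported.
#'
#' @param params Template parameters.
#' @param spontaneous_rates Per-column spontaneous geniculate rates, Hz
#'   (>= the 14 Hz baseline).
#' @param grid_spacing Cortical grid spacing for the columns, deg.
#' @param ... Passed to [modulation_ratio()].
#' @return A list with pooled `ratio`, per-column results and
#'   `rectification_onset_contrast`.
#' @export
run_multi_column_modulation <- function(params,
                                        spontaneous_rates =
                                          seq(14, 70, length.out = 5),
                                        grid_spacing =
                                          params$cortical_grid_spacing,
                                        ...) {
  stopifnot(all(spontaneous_rates >= 14))
  sens <- modelled_geniculate_sensitivity(params)
  cols <- lapply(spontaneous_rates, function(r) {
    p <- params
    p$spontaneous_lgn_rate <- r
    p$p0_sub <- r / p$g_rect
    p$subcortical_rectification_enabled <- TRUE
    net <- build_network(p, grid_spacing = grid_spacing)
    modulation_ratio(net, ...)
  })
  list(spontaneous_rates = spontaneous_rates,
       rectification_onset_contrast = spontaneous_rates / sens$sensitivity,
       ratio = unlist(lapply(cols, `[[`, "ratio")),
       columns = cols)
}

#' Modelled geniculate contrast sensitivity at the optimal spatial frequency
#'
#' Rate sensitivity of the geniculate centre-surround mechanism for a
#' grating at the model's optimal spatial frequency: the
#' difference-of-Gaussians attenuation (surround antagonising centre)
#' evaluated at the optimum, converted to Hz through the generator gain.
#' With the published parameters this is close to 280 Hz per contrast-unit,
#' down from the uniform-field maximum of about 450.
#'
#' @param params A `v1_params`; the surround is included in the sensitivity
#'   regardless of the basic-model flag.
#' @param spatial_frequency Cycles/deg; `NULL` uses the optimum of the
#'   basic-model tuning curve computed analytically.
#' @return List with `spatial_frequency` (cycles/deg), `sensitivity`
#'   (Hz per contrast-unit) and `max_sensitivity` (`g_cen * g_rect`).
#' @export
modelled_geniculate_sensitivity <- function(params,
                                            spatial_frequency = NULL) {
  if (is.null(spatial_frequency)) {
    basic <- params
    basic$surround_enabled <- FALSE
    net <- build_network(basic, cortical_stages = 1, single_cell = TRUE)
    spatial_frequency <- optimal_spatial_frequency_analytic(net)
  }
  with_sur <- params
  with_sur$surround_enabled <- TRUE
  a <- dog_attenuation(2 * pi * spatial_frequency, with_sur)
  list(spatial_frequency = spatial_frequency,
       sensitivity = a * params$g_rect,
       max_sensitivity = params$g_cen * params$g_rect)
}
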