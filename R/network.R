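#' Channel layout of the sub-cortical pathways
#'
#' Positions, signs and time constants of the m sub-cortical channels. For
#' the basic two-channel model the on-centre channel sits at
#' (+spacing/2, 0) and the faster off-centre channel at (-spacing/2, 0).
#' The six-channel variant places three on-centre cells in a vertical line
#' at +spacing/2 and three off-centre cells at -spacing/2, with same-sign
#' neighbours `elongation_spacing` apart, producing elongated subfields.
#'
#' @param params A `v1_params` object.
#' @return Data frame with columns `x`, `y` (deg), `sign` (+1 on, -1 off)
#'   and `tau` (ms).
#' @export
channel_layout <- function(params) {
  validate_parameters(params)
  d <- params$opposite_sign_spacing
  if (params$m == 2L) {
    data.frame(x = c(d / 2, -d / 2), y = c(0, 0), sign = c(1, -1),
               tau = c(params$tau_on, params$tau_off))
  } else {
    e <- params$elongation_spacing
    data.frame(x = rep(c(d / 2, -d / 2), each = 3),
               y = rep(c(-e, 0, e), 2),
               sign = rep(c(1, -1), each = 3),
               tau = rep(c(params$tau_on, params$tau_off), each = 3))
  }
}

#' Rectifying generator function
#'
#' Converts generator potential (membrane potential relative to
#' action-potential threshold) to impulse rate: zero below threshold,
#' proportional above it.
#'
#' @param p Generator potential, mV (vector or matrix).
#' @param g_rect Generator gain, Hz/mV.
#' @return Impulse rate, Hz, same shape as `p`.
#' @examples
#' rectify(c(-5, 0, 1), 7.2)
#' @export
rectify <- function(p, g_rect = 7.2) {
  pmax(p, 0) * g_rect
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Difference-of-Gaussians Fourier attenuation
#'
#' Spatial sensitivity of the sub-cortical receptive field to a sinusoidal
#' grating of spatial angular frequency `omega_s`. Each mechanism's Gaussian
#' is unit-normalised in two dimensions, so the uniform-field (omega_s = 0)
#' sensitivity equals the mechanism gain and the grating sensitivity is the
#' gain times `exp(-(omega_s * r / 2)^2)`. When the surround is disabled
#' only the centre term is returned.
#'
#' @param omega_s Spatial frequency, radians/deg (vector).
#' @param params A `v1_params` object.
#' @return Sensitivity, mV per contrast-unit.
#' @export
dog_attenuation <- function(omega_s, params) {
  a <- params$g_cen * exp(-(omega_s * params$r_cen / 2)^2)
  if (params$surround_enabled)
    a <- a - params$g_sur * exp(-(omega_s * params$r_sur / 2)^2)
  a
}

#' Sub-cortical spatial drive of one channel
#'
#' Evaluates the stimulus drive at the front of a sub-cortical channel: the
#' channel sign times the difference between the centre- and
#' surround-Gaussian spatial pools of the contrast field, evaluated at the
#' channel's receptive-field centre. All sub-cortical spatial convergence is
#' collapsed into this first stage. The pooling integrals are evaluated in
#' closed form: Fourier attenuation for gratings and error-function edge
#' integrals for rectangles; no spatial grid is involved.
#'
#' @param stimulus A `v1_stimulus`.
#' @param channel One row of [channel_layout()] (list/data.frame with `x`,
#'   `y`, `sign`).
#' @param t Times, s (vector).
#' @param params A `v1_params` object.
#' @return Drive in mV, one value per time.
#' @export
dog_drive <- function(stimulus, channel, t, params) {
  n_i <- channel$sign
  xi <- channel$x
  yi <- channel$y
  if (stimulus$kind == "drifting_grating") {
    a <- dog_attenuation(stimulus$omega_s, params)
    u <- xi * cos(stimulus$theta) + yi * sin(stimulus$theta)
    n_i * a * stimulus$contrast *
      sin(stimulus$omega_s * u - stimulus$drift_sign * stimulus$omega_t * t +
            stimulus$phase)
  } else if (stimulus$kind == "contrast_reversing_grating") {
    a <- dog_attenuation(stimulus$omega_s, params)
    u <- xi * cos(stimulus$theta) + yi * sin(stimulus$theta)
    n_i * a * stimulus$contrast *
      sin(stimulus$omega_s * u + stimulus$phase) * sin(stimulus$omega_t * t)
  } else {
    # rectangle: separable product of 1-D Gaussian integrals over the edges
    th <- stimulus$theta
    u <- (xi - stimulus$x) * cos(th) + (yi - stimulus$y) * sin(th)
    v <- -(xi - stimulus$x) * sin(th) + (yi - stimulus$y) * cos(th)
    q <- function(z, halfwidth, r)
      0.5 * (erf((z + halfwidth) / r) - erf((z - halfwidth) / r))
    pool <- function(r)
      q(u, stimulus$width / 2, r) * q(v, stimulus$height / 2, r)
    a <- params$g_cen * pool(params$r_cen)
    if (params$surround_enabled) a <- a - params$g_sur * pool(params$r_sur)
    on_window <- as.numeric(t >= stimulus$onset &
                              t < stimulus$onset + stimulus$duration)
    n_i * a * stimulus$contrast * on_window
  }
}

#' Sub-cortical drive by numerical quadrature
#'
#' Pixel-grid evaluation of the same pooling integral as [dog_drive()], for
#' arbitrary stimuli and as an accuracy check on the closed forms (the two
#' agree to better than 0.1 percent at the default resolution).
#'
#' @inheritParams dog_drive
#' @param grid_n Quadrature points per axis.
#' @param span Half-width of the quadrature window, in surround radii.
#' @return Drive in mV, one value per time.
#' @export
dog_drive_numeric <- function(stimulus, channel, t, params,
                              grid_n = 301, span = 4) {
  # midpoint quadrature on a domain where the integrand is smooth:
  # the kernel window for gratings, the stimulus support for spots/bars
  if (stimulus$kind %in% c("spot", "bar")) {
    th <- stimulus$theta
    mid <- function(halfwidth)
      seq(-halfwidth + halfwidth / grid_n, halfwidth - halfwidth / grid_n,
          length.out = grid_n)
    us <- mid(stimulus$width / 2)
    vs <- mid(stimulus$height / 2)
    hu <- stimulus$width / grid_n
    hv <- stimulus$height / grid_n
    uu <- rep(us, times = grid_n)
    vv <- rep(vs, each = grid_n)
    px <- stimulus$x + uu * cos(th) - vv * sin(th)
    py <- stimulus$y + uu * sin(th) + vv * cos(th)
    d2 <- (px - channel$x)^2 + (py - channel$y)^2
    kern <- function(r) sum(exp(-d2 / r^2)) / (pi * r^2) * hu * hv
    a <- params$g_cen * kern(params$r_cen)
    if (params$surround_enabled) a <- a - params$g_sur * kern(params$r_sur)
    on_win <- as.numeric(t >= stimulus$onset &
                           t < stimulus$onset + stimulus$duration)
    channel$sign * stimulus$contrast * a * on_win
  } else {
    half <- span * params$r_sur
    xs <- seq(-half, half, length.out = grid_n)
    h <- xs[2] - xs[1]
    gx <- rep(xs, times = grid_n)
    gy <- rep(xs, each = grid_n)
    kc <- exp(-(gx^2 + gy^2) / params$r_cen^2) /
      (pi * params$r_cen^2) * h^2
    ks <- if (params$surround_enabled)
      exp(-(gx^2 + gy^2) / params$r_sur^2) / (pi * params$r_sur^2) * h^2
    else NULL
    vapply(t, function(tt) {
      cfield <- evaluate_contrast(stimulus, channel$x + gx,
                                  channel$y + gy, tt)
      a <- params$g_cen * sum(kc * cfield)
      if (!is.null(ks)) a <- a - params$g_sur * sum(ks * cfield)
      channel$sign * a
    }, numeric(1))
  }
}

cortical_gaussian_weights <- function(from_pos, to_pos, r, gain,
                                      normalise = FALSE) {
  d2 <- outer(to_pos[, 1], from_pos[, 1], "-")^2 +
    outer(to_pos[, 2], from_pos[, 2], "-")^2
  w <- exp(-d2 / r^2)
  if (normalise) w <- w / rowSums(w)
  gain * w
}

#' Build the column network
#'
#' Assembles the full feedforward network: m sub-cortical channels of four
#' neurons each (photoreceptor, bipolar, ganglion cell, geniculate relay
#' cell) followed by up to three cortical stages of neurons on a square grid
#' spanning the visual-field patch.
#'
#' Geniculocortical weights are `g_GC * exp(-(d/r_cort)^2)` with `d` the
#' distance between the cortical cell and the channel centre. Intracortical
#' weights are Gaussian with the same radius, truncated at the patch
#' boundary and renormalised per neuron to sum to `g_cort`, which removes
#' edge artefacts from the (nearly uniform) convergence. The stage-1
#' cortical static polarisation is set per neuron so that every cell rests
#' the same distance below threshold regardless of its position relative to
#' the channels.
#'
#' @param params A `v1_params` object.
#' @param cortical_stages Number of cortical stages to build (1-3). Building
#'   only stage 1 is cheaper when later stages are not analysed.
#' @param grid_spacing Cortical grid spacing, deg.
#' @param single_cell If `TRUE`, each cortical stage contains a single
#'   neuron at the patch centre (the "centrally located" cell of the
#'   single-neuron experiments).
#' @return A `v1_network` object.
#' @examples
#' net <- build_network(model_parameters(), cortical_stages = 1,
#'                      single_cell = TRUE)
#' net$n_state
#' @export
build_network <- function(params, cortical_stages = 3,
                          grid_spacing = params$cortical_grid_spacing,
                          single_cell = FALSE) {
  validate_parameters(params)
  stopifnot(cortical_stages >= 1, cortical_stages <= 3)
  lay <- channel_layout(params)
  m <- nrow(lay)
  half <- params$patch_side / 2
  pos <- if (single_cell) matrix(0, 1, 2) else {
    xs <- seq(-half, half, by = grid_spacing)
    cbind(rep(xs, times = length(xs)), rep(xs, each = length(xs)))
  }
  n_c <- nrow(pos)
  # geniculocortical weights (not normalised; Table-1 g_GC absorbs scale)
  W5 <- cortical_gaussian_weights(as.matrix(lay[, c("x", "y")]), pos,
                                  params$r_cort, params$g_GC)
  # stage-1 static polarisation: uniform resting distance below threshold
  v_rmt <- params$resting_minus_threshold_stage1
  if (is.null(v_rmt)) {
    w0 <- params$g_GC * exp(-((lay$x^2 + lay$y^2) / params$r_cort^2))
    v_rmt <- params$p0_stage1 + params$p0_sub * sum(w0)
  }
  if (v_rmt >= 0)
    stop("invalid parameters: implied stage-1 resting potential is not ",
         "hyperpolarised", call. = FALSE)
  p0_c1 <- v_rmt - params$p0_sub * rowSums(W5)
  stages <- list(cortex1 = list(pos = pos, W = W5, p0 = p0_c1))
  if (cortical_stages >= 2)
    stages$cortex2 <- list(
      pos = pos,
      W = cortical_gaussian_weights(pos, pos, params$r_cort, params$g_cort,
                                    normalise = TRUE),
      p0 = rep(params$p0_late, n_c))
  if (cortical_stages >= 3)
    stages$cortex3 <- list(
      pos = pos,
      W = cortical_gaussian_weights(pos, pos, params$r_cort, params$g_cort,
                                    normalise = TRUE),
      p0 = rep(params$p0_late, n_c))
  n_sub <- 4L * m
  idx <- list(sub = seq_len(n_sub))
  off <- n_sub
  for (s in names(stages)) {
    idx[[s]] <- off + seq_len(nrow(stages[[s]]$pos))
    off <- off + nrow(stages[[s]]$pos)
  }
  net <- list(params = params, layout = lay, m = m, stages = stages,
              idx = idx, n_state = off,
              central = which.min(pos[, 1]^2 + pos[, 2]^2),
              resting_minus_threshold_stage1 = v_rmt)
  class(net) <- "v1_network"
  net
}

#' @export
print.v1_network <- function(x, ...) {
  cat("Feedforward column network:", x$m, "sub-cortical channels,",
      length(x$stages), "cortical stage(s) of",
      nrow(x$stages$cortex1$pos), "neuron(s);",
      x$n_state, "state variables\n")
  invisible(x)
}

relay_output <- function(net, p_relay) {
  if (net$params$subcortical_rectification_enabled) pmax(p_relay, 0)
  else p_relay
}

#' Right-hand side of the sub-cortical dynamics
#'
#' Growth rates of the generator potentials in the four neurons of every
#' sub-cortical channel. Each neuron is a first-order low-pass filter with
#' the channel time constant; the first neuron is driven by the spatially
#' pooled stimulus plus the sub-cortical static polarisation, and later
#' neurons are driven by their predecessor. In the basic model the
#' inter-stage signals are graded potentials; with sub-cortical
#' rectification enabled the ganglion-to-relay signal is half-wave
#' rectified.
#'
#' @param state Numeric vector of the 4m sub-cortical potentials, channel
#'   by channel (photoreceptor, bipolar, ganglion, relay).
#' @param stimulus A `v1_stimulus`.
#' @param t Time, s (scalar).
#' @param network A `v1_network`.
#' @return Vector of time derivatives, mV/s.
#' @export
subcortical_rhs <- function(state, stimulus, t, network) {
  params <- network$params
  m <- network$m
  drv <- vapply(seq_len(m), function(i)
    dog_drive(stimulus, network$layout[i, ], t, params), numeric(1))
  p <- matrix(state, nrow = 4L)          # stage x channel
  tau <- network$layout$tau / 1000       # ms -> s
  gang_out <- if (params$subcortical_rectification_enabled)
    pmax(p[3L, ], 0) else p[3L, ]
  dp <- rbind(drv + params$p0_sub - p[1L, ],
              p[1L, ] - p[2L, ],
              p[2L, ] - p[3L, ],
              gang_out - p[4L, ])
  as.vector(dp) / rep(tau, each = 4L)
}

#' Right-hand side of the cortical dynamics
#'
#' Growth rates of the cortical generator potentials given the full network
#' state. Stage-1 cortical neurons weight the geniculate relay outputs
#' (graded in the basic model, rectified when sub-cortical rectification is
#' enabled); later stages weight the rectified potentials of the previous
#' stage, so the effective synaptic drive is the presynaptic potential
#' clipped at zero.
#'
#' @param state Full network state vector (sub-cortical then cortical
#'   potentials).
#' @param t Time, s (unused; the cortical drive depends only on the state).
#' @param network A `v1_network`.
#' @return Vector of time derivatives for the cortical potentials, mV/s.
#' @export
cortical_rhs <- function(state, t, network) {
  params <- network$params
  tau <- params$tau_cort / 1000
  relay <- state[network$idx$sub][4L * seq_len(network$m)]
  pre <- relay_output(network, relay)
  out <- numeric(0)
  for (s in names(network$stages)) {
    st <- network$stages[[s]]
    p <- state[network$idx[[s]]]
    out <- c(out, (as.vector(st$W %*% pre) + st$p0 - p) / tau)
    pre <- pmax(p, 0)
  }
  out
}

#' Closed-form resting state of the network
#'
#' Fixed point of the dynamics with zero stimulus. All sub-cortical
#' potentials rest at the sub-cortical static polarisation (giving the
#' spontaneous geniculate rate); stage-1 cortical cells rest below threshold
#' (zero spontaneous rate); stage-2 cells rest at the late static
#' polarisation, and stage-3 cells additionally receive the stage-2
#' spontaneous drive.
#'
#' @param network A `v1_network`.
#' @return List with `potentials` (full state vector, mV) and `rates` (Hz).
#' @export
resting_state <- function(network) {
  params <- network$params
  p <- numeric(network$n_state)
  p[network$idx$sub] <- params$p0_sub
  relay <- rep(params$p0_sub, network$m)
  pre <- relay_output(network, relay)
  for (s in names(network$stages)) {
    st <- network$stages[[s]]
    p[network$idx[[s]]] <- as.vector(st$W %*% pre) + st$p0
    pre <- pmax(p[network$idx[[s]]], 0)
  }
  rates <- rectify(p, params$g_rect)
  # photoreceptors and bipolar cells emit graded potentials, not impulses
  graded <- network$idx$sub[rep(c(TRUE, TRUE, FALSE, FALSE), network$m)]
  rates[graded] <- NA_real_
  list(potentials = p, rates = rates)
}

#' Spatial derivative approximation of the cortical subunit profile
#'
#' The first-stage cortical cell differences two centre-Gaussian profiles a
#' small distance apart, which approximates the spatial derivative of a
#' single centre profile. Returns the relative L2 distance between the
#' on-minus-inverted-off profile sum and the derivative of one profile
#' scaled by the separation, on a 1-D transect.
#'
#' @param separation Distance between the on- and off-centre profiles, deg.
#' @param radius Centre-mechanism 1/e radius, deg.
#' @param n Transect samples.
#' @param span Transect half-width, deg.
#' @return Relative L2 error (dimensionless).
#' @export
spatial_profile_and_derivative_check <- function(separation = 0.1,
                                                 radius = 0.4,
                                                 n = 2001, span = 2) {
  x <- seq(-span, span, length.out = n)
  g <- function(x) exp(-(x / radius)^2)
  s <- g(x - separation / 2) - g(x + separation / 2)
  d <- separation * (2 * x / radius^2) * g(x)
  rel_l2 <- sqrt(sum((s - d)^2) / sum(d^2))
  rel_l2
}

#' Impulse response of a low-pass filter cascade
#'
#' A cascade of `shape` identical first-order low-pass filters has a
#' gamma-density impulse response with shape factor `shape` and the given
#' time constant; it peaks at `(shape - 1) * tau`.
#'
#' @param t Time, ms (vector).
#' @param tau Time constant, ms.
#' @param shape Number of cascaded filters.
#' @return Impulse response values (1/ms units).
#' @export
cascade_impulse_response <- function(t, tau = 10, shape = 4) {
  stats::dgamma(t, shape = shape, scale = tau)
}

#' Temporal derivative approximation of the geniculate input difference
#'
#' The difference between the on- and off-relay impulse responses (gamma
#' densities of the given shape with time constants `tau_on` and `tau_off`)
#' is compared with the derivative of a single gamma density with respect to
#' its time constant, taken at the mean time constant and scaled by the
#' time-constant difference.
#'
#' @param tau_on,tau_off Channel time constants, ms.
#' @param shape Cascade length (4: photoreceptor to relay cell).
#' @param n Time samples.
#' @param t_max End of the time window, ms.
#' @return Relative L2 error (dimensionless; 0 when the time constants are
#'   equal).
#' @export
temporal_profile_and_derivative_check <- function(tau_on = 11, tau_off = 9,
                                                  shape = 4, n = 3001,
                                                  t_max = 200) {
  t <- seq(0, t_max, length.out = n)
  s <- cascade_impulse_response(t, tau_on, shape) -
    cascade_impulse_response(t, tau_off, shape)
  tau_mid <- (tau_on + tau_off) / 2
  dtau <- tau_on - tau_off
  d <- dtau * cascade_impulse_response(t, tau_mid, shape) *
    (t - shape * tau_mid) / tau_mid^2
  if (sum(d^2) == 0 && sum(s^2) == 0) return(0)
  sqrt(sum((s - d)^2) / sum(d^2))
}
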