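#' @importFrom deSolve ode
NULL

# Precompute a fast drive function: t (vector, s) -> matrix [time x channel]
make_drive_fn <- function(network, stimulus) {
  params <- network$params
  lay <- network$layout
  m <- network$m
  if (stimulus$kind == "drifting_grating") {
    a <- dog_attenuation(stimulus$omega_s, params)
    u <- lay$x * cos(stimulus$theta) + lay$y * sin(stimulus$theta)
    amp <- lay$sign * a * stimulus$contrast
    sp <- stimulus$omega_s * u + stimulus$phase
    s <- stimulus$drift_sign
    wt <- stimulus$omega_t
    function(t) {
      ph <- outer(-s * wt * t, sp, "+")
      sin(ph) * rep(amp, each = length(t))
    }
  } else if (stimulus$kind == "contrast_reversing_grating") {
    a <- dog_attenuation(stimulus$omega_s, params)
    u <- lay$x * cos(stimulus$theta) + lay$y * sin(stimulus$theta)
    k <- lay$sign * a * stimulus$contrast *
      sin(stimulus$omega_s * u + stimulus$phase)
    wt <- stimulus$omega_t
    function(t) outer(sin(wt * t), k)
  } else {
    amp <- vapply(seq_len(m), function(i)
      dog_drive(stimulus, lay[i, ], stimulus$onset, params), numeric(1))
    on0 <- stimulus$onset
    on1 <- stimulus$onset + stimulus$duration
    function(t) outer(as.numeric(t >= on0 & t < on1), amp)
  }
}

#' Simulate the network response to a stimulus
#'
#' Integrates the coupled generator-potential equations from the resting
#' state and samples the solution on a uniform grid. Two engines are
#' available: `"ode45"`, adaptive Dormand-Prince Runge-Kutta (4,5)
#' integration of the full coupled system, split at stimulus on/offset
#' discontinuities; and `"staged"`, an exact-exponential integrator that
#' exploits the strictly feedforward architecture by solving each stage's
#' scalar linear equations sequentially on the output grid (second-order in
#' the grid step for smooth drive, exact for flashed stimuli). The two
#' engines agree to solver tolerance and the staged engine is much faster
#' for large cortical grids.
#'
#' @param network A `v1_network`.
#' @param stimulus A `v1_stimulus`.
#' @param duration Simulated time span, s. For periodic stimuli use at least
#'   three temporal cycles so that a transient cycle can be discarded.
#' @param dt Output sampling interval, s (default 1 ms).
#' @param engine `"ode45"` or `"staged"`.
#' @param rtol,atol Relative and absolute (mV) tolerances for the adaptive
#'   integrator.
#' @param initial Optional initial state vector; defaults to
#'   [resting_state()].
#' @return A `v1_simulation` with `times` (s), `potentials` and `rates`
#'   (time x neuron matrices; rates are the rectified potentials, `NA` for
#'   the non-spiking photoreceptors and bipolar cells), the stimulus, and
#'   solver metadata.
#' @examples
#' net <- build_network(model_parameters(), cortical_stages = 1,
#'                      single_cell = TRUE)
#' sim <- simulate_network(net, spot_stimulus(), duration = 0.2)
#' max(sim$rates[, state_index(net, "cortex1")])
#' @export
simulate_network <- function(network, stimulus, duration,
                             dt = 0.001, engine = c("ode45", "staged"),
                             rtol = 1e-6, atol = 1e-9, initial = NULL) {
  engine <- match.arg(engine)
  stopifnot(duration > 0)
  y0 <- if (is.null(initial)) resting_state(network)$potentials
  else initial
  stopifnot(length(y0) == network$n_state)
  grid <- seq(0, duration, by = dt)
  if (grid[length(grid)] < duration) grid <- c(grid, duration)
  bp <- stimulus_breakpoints(stimulus)
  bp <- bp[bp > 0 & bp < duration]
  times <- sort(unique(c(grid, bp)))
  pot <- if (engine == "ode45")
    integrate_ode45(network, stimulus, times, y0, bp, rtol, atol)
  else
    integrate_staged(network, stimulus, times, y0)
  if (anyNA(pot)) stop("integration error: NaN in state", call. = FALSE)
  rates <- rectify(pot, network$params$g_rect)
  graded <- network$idx$sub[rep(c(TRUE, TRUE, FALSE, FALSE), network$m)]
  rates[, graded] <- NA_real_
  out <- list(times = times, potentials = pot, rates = rates,
              stimulus = stimulus, network = network,
              solver = list(engine = engine, dt = dt, rtol = rtol,
                            atol = atol))
  class(out) <- "v1_simulation"
  out
}

integrate_ode45 <- function(network, stimulus, times, y0, bp, rtol, atol) {
  drive_fn <- make_drive_fn(network, stimulus)
  params <- network$params
  m <- network$m
  tau_sub <- rep(network$layout$tau / 1000, each = 4L)
  sub_rect <- params$subcortical_rectification_enabled
  rhs <- function(t, y, parms) {
    drv <- drive_fn(t)[1L, ]
    p <- matrix(y[network$idx$sub], nrow = 4L)
    gang <- if (sub_rect) pmax(p[3L, ], 0) else p[3L, ]
    dsub <- as.vector(rbind(drv + params$p0_sub - p[1L, ],
                            p[1L, ] - p[2L, ],
                            p[2L, ] - p[3L, ],
                            gang - p[4L, ])) / tau_sub
    list(c(dsub, cortical_rhs(y, t, network)))
  }
  segs <- sort(unique(c(0, bp, times[length(times)])))
  out <- matrix(NA_real_, length(times), network$n_state)
  out[1L, ] <- y0
  y <- y0
  for (k in seq_len(length(segs) - 1L)) {
    tt <- times[times >= segs[k] & times <= segs[k + 1L]]
    if (tt[1L] > segs[k]) tt <- c(segs[k], tt)
    sol <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = "ode45", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("integration error: solver failed in segment ", k,
           call. = FALSE)
    y <- as.numeric(sol[nrow(sol), -1L])
    keep <- match(tt, times)
    ok <- !is.na(keep)
    out[keep[ok], ] <- sol[ok, -1L, drop = FALSE]
  }
  out
}

# Exact-exponential staged integrator for the feedforward cascade.
# Scalar linear stages p' = (u(t) - p)/tau are advanced with
#   p_{k+1} = E p_k + c0 u_k + c1 u_{k+1},  E = exp(-h/tau)
# where (c0, c1) interpolate the forcing linearly (exact for constant u).
integrate_staged <- function(network, stimulus, times, y0) {
  params <- network$params
  m <- network$m
  nt <- length(times)
  h <- diff(times)
  drive <- make_drive_fn(network, stimulus)(times)   # nt x m
  boxcar <- stimulus$kind %in% c("spot", "bar")
  coefs <- function(tau) {                # tau in s; per-step coefficients
    e <- exp(-h / tau)
    a <- 1 - e
    b <- 1 - (tau / h) * a
    list(e = e, c0 = a - b, c1 = b, a = a)
  }
  recur <- function(u, cf, p1, constant = FALSE) {
    # u: nt x n forcing; returns nt x n potential series
    n <- ncol(u)
    p <- matrix(0, nt, n)
    p[1L, ] <- p1
    if (constant) {
      for (k in 2:nt)
        p[k, ] <- cf$e[k - 1L] * p[k - 1L, ] + cf$a[k - 1L] * u[k - 1L, ]
    } else {
      for (k in 2:nt)
        p[k, ] <- cf$e[k - 1L] * p[k - 1L, ] +
          cf$c0[k - 1L] * u[k - 1L, ] + cf$c1[k - 1L] * u[k, ]
    }
    p
  }
  pot <- matrix(NA_real_, nt, network$n_state)
  rest <- y0
  # sub-cortical channels
  for (i in seq_len(m)) {
    cf <- coefs(network$layout$tau[i] / 1000)
    cols <- network$idx$sub[(i - 1L) * 4L + 1:4]
    u <- drive[, i, drop = FALSE] + params$p0_sub
    s1 <- recur(u, cf, rest[cols[1L]], constant = boxcar)
    s2 <- recur(s1, cf, rest[cols[2L]])
    s3 <- recur(s2, cf, rest[cols[3L]])
    g <- if (params$subcortical_rectification_enabled) pmax(s3, 0) else s3
    s4 <- recur(g, cf, rest[cols[4L]])
    pot[, cols] <- cbind(s1, s2, s3, s4)
  }
  relay <- pot[, network$idx$sub[4L * seq_len(m)], drop = FALSE]
  pre <- if (params$subcortical_rectification_enabled) pmax(relay, 0)
  else relay
  cfc <- coefs(params$tau_cort / 1000)
  for (s in names(network$stages)) {
    st <- network$stages[[s]]
    u <- pre %*% t(st$W) + rep(st$p0, each = nt)
    pot[, network$idx[[s]]] <- recur(u, cfc, rest[network$idx[[s]]])
    pre <- pmax(pot[, network$idx[[s]], drop = FALSE], 0)
  }
  pot
}

#' State-vector indices for a stage
#'
#' @param network A `v1_network`.
#' @param stage `"sub"`, `"relay"` (the geniculate relay cells only),
#'   `"cortex1"`, `"cortex2"` or `"cortex3"`.
#' @param neuron Optional neuron index within the stage; `"central"` picks
#'   the neuron nearest the patch centre.
#' @return Integer column indices into the simulation matrices.
#' @export
state_index <- function(network, stage = "cortex1", neuron = NULL) {
  idx <- if (stage == "relay")
    network$idx$sub[4L * seq_len(network$m)]
  else network$idx[[stage]]
  if (is.null(idx)) stop("unknown stage: ", stage, call. = FALSE)
  if (is.null(neuron)) return(idx)
  if (identical(neuron, "central")) {
    if (stage %in% c("sub", "relay")) stop("'central' needs a cortical stage")
    return(idx[network$central])
  }
  idx[neuron]
}

#' Analytic steady-state response in the linear regime
#'
#' Closed-form fundamental response of the pre-rectification dynamics to a
#' grating: each channel's drive phasor (difference-of-Gaussians attenuation
#' at the grating spatial frequency, with the spatial phase set by the
#' channel position) is passed through the cascade transfer function
#' `1/(1 + i omega tau)` per neuron, summed over channels with the
#' geniculocortical weights, and filtered once more by the cortical time
#' constant. Valid when contrast is low enough that no rectification
#' occurs up to the first cortical stage (caller-asserted); serves as the
#' independent oracle for [simulate_network()].
#'
#' The returned complex amplitude `Z` describes the steady-state potential
#' `p(t) = rest + |Z| * sin(omega_t * t + Arg(Z))`.
#'
#' @param network A `v1_network`.
#' @param stimulus A drifting grating (for a contrast-reversing grating the
#'   same cascade applies to its standing-wave phasor).
#' @param stage `"relay"` (per channel) or `"cortex1"` (per stage-1 neuron).
#' @return Complex vector of fundamental amplitudes (mV).
#' @export
analytic_linear_response <- function(network, stimulus, stage = "cortex1") {
  if (!stimulus$kind %in% c("drifting_grating", "contrast_reversing_grating"))
    stop("unsupported stimulus for the analytic oracle: ", stimulus$kind,
         call. = FALSE)
  params <- network$params
  lay <- network$layout
  a <- dog_attenuation(stimulus$omega_s, params)
  u <- lay$x * cos(stimulus$theta) + lay$y * sin(stimulus$theta)
  z_drive <- if (stimulus$kind == "drifting_grating") {
    beta <- if (stimulus$drift_sign > 0)
      pi - (stimulus$omega_s * u + stimulus$phase)
    else stimulus$omega_s * u + stimulus$phase
    lay$sign * a * stimulus$contrast * exp(1i * beta)
  } else {
    lay$sign * a * stimulus$contrast *
      sin(stimulus$omega_s * u + stimulus$phase) + 0i
  }
  w <- stimulus$omega_t
  h_sub <- (1 + 1i * w * lay$tau / 1000)^(-4)
  z_relay <- z_drive * h_sub
  if (stage == "relay") return(z_relay)
  if (stage != "cortex1")
    stop("the linear oracle covers stages up to cortex1", call. = FALSE)
  h_cort <- 1 / (1 + 1i * w * params$tau_cort / 1000)
  as.vector(network$stages$cortex1$W %*% z_relay) * h_cort
}

#' Fundamental Fourier components of a response trace
#'
#' Projects a periodic steady-state trace onto its mean and fundamental.
#' The first `discard_cycles` temporal cycles are dropped as transient and
#' an integer number (at least 2) of the remaining cycles is analysed.
#' Phase follows the sine convention: the trace is represented as
#' `f0 + f1_amplitude * sin(2 pi frequency t + f1_phase)`.
#'
#' @param x Response samples.
#' @param times Sample times, s (uniform grid).
#' @param frequency Analysis frequency, Hz.
#' @param discard_cycles Transient cycles to drop (default 1).
#' @return A list with `f0`, `f1_amplitude`, `f1_phase` (in (-pi, pi]),
#'   `frequency` and `n_cycles`.
#' @examples
#' t <- seq(0, 2, by = 0.001)
#' fourier_components(3 + 2 * sin(2 * pi * 4 * t), t, 4, discard_cycles = 0)
#' @export
fourier_components <- function(x, times, frequency, discard_cycles = 1) {
  stopifnot(length(x) == length(times), frequency > 0)
  period <- 1 / frequency
  t0 <- times[1] + discard_cycles * period
  span <- times[length(times)] - t0
  n_cycles <- floor(span / period + 1e-9)
  if (n_cycles < 2)
    stop("analysis error: trace covers fewer than 2 cycles after the ",
         "transient", call. = FALSE)
  t_end <- t0 + n_cycles * period
  keep <- times >= t0 - 1e-12 & times < t_end - 1e-12
  x <- x[keep]
  tt <- times[keep]
  w <- 2 * pi * frequency
  f0 <- mean(x)
  a <- 2 * mean(x * sin(w * tt))
  b <- 2 * mean(x * cos(w * tt))
  list(f0 = f0, f1_amplitude = sqrt(a^2 + b^2), f1_phase = atan2(b, a),
       frequency = frequency, n_cycles = n_cycles)
}

#' @export
print.v1_simulation <- function(x, ...) {
  cat("Simulation:", x$stimulus$kind, "stimulus,",
      sprintf("%.3g s in %d samples,", x$times[length(x$times)],
              length(x$times)),
      ncol(x$potentials), "neurons, engine", x$solver$engine, "\n")
  invisible(x)
}
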