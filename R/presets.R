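# Experiment presets, run configuration and result persistence.

#' Catalogue of figure-level experiment presets
#'
#' One preset per in-silico experiment panel, with the stimulus and model
#' variant fixed to the published protocol: spot maps for stage-1 and
#' stage-3 receptive fields (basic and six-channel variants), orientation
#' and spatial-frequency tuning with population histograms, direction
#' selectivity for single and multiple columns, the spatiotemporal
#' bar map, the contrast-reversing phase scan, modulation ratios with and
#' without sub-cortical rectification, and the derivative-approximation
#' checks.
#'
#' @return Named list of preset definitions (experiment name, variant and
#'   experiment arguments).
#' @examples
#' names(list_presets())
#' @export
list_presets <- function() {
  list(
    fig2c = list(experiment = "rf_map", variant = "basic",
                 stage = "cortex1",
                 args = list(spot_side = 0.38, grid_n = 16,
                             readout = "peak")),
    fig2d = list(experiment = "rf_map", variant = "basic",
                 stage = "cortex3",
                 args = list(spot_side = 0.38, grid_n = 16,
                             readout = "peak")),
    fig2f = list(experiment = "rf_map", variant = "six_channel",
                 stage = "cortex1",
                 args = list(spot_side = 0.8, grid_n = 16,
                             readout = "peak")),
    fig3a = list(experiment = "orientation", variant = "basic",
                 stage = "cortex1",
                 args = list(spatial_frequency = 0.49, contrast = 0.3)),
    fig3a_6ch = list(experiment = "orientation", variant = "six_channel",
                     stage = "cortex1",
                     args = list(spatial_frequency = 0.49, contrast = 0.3)),
    fig3b = list(experiment = "sf_tuning", variant = "basic",
                 stage = "cortex1", args = list(contrast = 0.3)),
    fig3b_surround = list(experiment = "sf_tuning",
                          variant = "basic_surround", stage = "cortex1",
                          args = list(contrast = 0.3)),
    fig4c = list(experiment = "dsi", variant = "basic", stage = "cortex1",
                 args = list(contrast = 0.3)),
    fig4c_multicolumn = list(experiment = "dsi_multicolumn",
                             variant = "basic", stage = "cortex1",
                             args = list(n_columns = 10,
                                         delta_tau_range = c(0, 2))),
    fig5a = list(experiment = "strf", variant = "six_channel",
                 stage = "cortex1",
                 args = list(n_locations = 16, bar_width = 0.25)),
    fig5b = list(experiment = "phase_scan", variant = "basic",
                 stage = "cortex1", args = list(contrast = 1)),
    fig6 = list(experiment = "modulation", variant = "basic",
                stage = "all", args = list(contrast = 0.25)),
    fig6_rectified = list(experiment = "modulation_multicolumn",
                          variant = "basic", stage = "all",
                          args = list(contrast = 0.25)),
    fig7_checks = list(experiment = "derivative_checks", variant = "basic",
                       stage = "cortex1", args = list())
  )
}

# presets run on the full-precision calibration chain; see
# calibrated_parameters() for why this matters for flashed stimuli
variant_params <- function(variant) {
  switch(variant,
         basic = calibrated_parameters(),
         basic_surround = calibrated_parameters(surround_enabled = TRUE),
         six_channel = calibrated_parameters(m = 6),
         stop("unknown variant: ", variant, call. = FALSE))
}

#' Run configuration
#'
#' Builds and validates a run configuration for [run_experiment()].
#'
#' @param preset Name from [list_presets()], or `NULL` to specify the
#'   experiment directly.
#' @param experiment Experiment name (ignored when a preset is given).
#' @param variant `"basic"`, `"basic_surround"` or `"six_channel"`.
#' @param stage Cortical stage analysed.
#' @param grid_spacing Cortical grid spacing, deg.
#' @param seed Integer seed (relevant to randomised multi-column runs).
#' @param out_dir Output directory.
#' @param args Extra arguments for the experiment function.
#' @return A `v1_run_config` list.
#' @export
run_config <- function(preset = NULL, experiment = NULL, variant = "basic",
                       stage = "cortex1", grid_spacing = 0.1, seed = 1,
                       out_dir = "v1column-output", args = list()) {
  if (!is.null(preset)) {
    pp <- list_presets()[[preset]]
    if (is.null(pp)) stop("unknown preset: ", preset, call. = FALSE)
    experiment <- pp$experiment
    variant <- pp$variant
    stage <- pp$stage
    args <- utils::modifyList(pp$args, args)
  }
  if (is.null(experiment))
    stop("either a preset or an experiment name is required", call. = FALSE)
  cfg <- list(preset = preset, experiment = experiment, variant = variant,
              stage = stage, grid_spacing = grid_spacing,
              seed = as.integer(seed), out_dir = out_dir, args = args)
  class(cfg) <- "v1_run_config"
  cfg
}

#' Write / read a run configuration
#'
#' YAML round-trip of a run configuration; reading re-validates through
#' [run_config()].
#'
#' @param config A `v1_run_config`.
#' @param path File path.
#' @return `path` (write) or a `v1_run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "v1_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' Run a configured experiment and persist its outputs
#'
#' Builds the configured network variant, runs the named experiment, and
#' writes its outputs (CSV curves/histograms, a JSON metric summary, and a
#' manifest listing every output file with its checksum) into the output
#' directory. Deterministic experiments reproduce their outputs exactly
#' when rerun with an identical configuration.
#'
#' @param config A `v1_run_config` (or a preset name).
#' @return Invisibly, the list of result objects; outputs are written to
#'   `config$out_dir`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- run_config(preset = config)
  stopifnot(inherits(config, "v1_run_config"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("run_experiment needs the 'jsonlite' package for JSON summaries",
         call. = FALSE)
  set.seed(config$seed)
  params <- variant_params(config$variant)
  params$cortical_grid_spacing <- config$grid_spacing
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_csv <- function(df, name) {
    f <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  put_json <- function(x, name) {
    f <- file.path(config$out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, f)
  }
  need_stages <- if (identical(config$stage, "all")) 3L
  else as.integer(sub("cortex", "", config$stage))
  build <- function(stages = need_stages)
    build_network(params, cortical_stages = stages,
                  grid_spacing = config$grid_spacing)
  res <- switch(
    config$experiment,
    rf_map = {
      r <- do.call(map_receptive_field,
                   c(list(network = build(), stage = config$stage),
                     config$args))
      put_csv(data.frame(x = rep(r$x, times = length(r$y)),
                         y = rep(r$y, each = length(r$x)),
                         light = as.vector(r$light),
                         dark = as.vector(r$dark)), "rf_map")
      put_json(list(overlap_index = r$overlap_index), "summary")
      r
    },
    orientation = {
      net <- build(1L)
      r <- do.call(orientation_tuning,
                   c(list(network = net, stage = config$stage),
                     config$args))
      put_csv(data.frame(direction_deg = r$abscissa,
                         elevation_hz = r$central_curve), "tuning_curve")
      put_csv(data.frame(half_width_deg = r$half_widths,
                         active = r$active), "half_widths")
      put_json(list(median_half_width_deg = r$median_half_width,
                    n_active = sum(r$active)), "summary")
      r
    },
    sf_tuning = {
      net <- build(1L)
      r <- do.call(spatial_frequency_tuning,
                   c(list(network = net, stage = config$stage),
                     config$args))
      put_csv(data.frame(spatial_frequency = r$abscissa,
                         elevation_hz = r$central_curve), "tuning_curve")
      put_csv(data.frame(bandwidth_octaves = r$bandwidths,
                         active = r$active), "bandwidths")
      put_json(list(optimum_cpd = r$optimum,
                    median_bandwidth_octaves = r$median_bandwidth),
               "summary")
      r
    },
    dsi = {
      net <- build(1L)
      r <- do.call(direction_selectivity,
                   c(list(network = net, stage = config$stage),
                     config$args))
      put_csv(data.frame(index_normalised = r$index_normalised_form,
                         index_ratio = r$index_ratio_form,
                         index_potential_normalised =
                           r$index_potential_normalised_form,
                         active = r$active), "direction_indices")
      put_json(list(spatial_frequency = r$spatial_frequency,
                    median_index =
                      stats::median(r$index_normalised_form[r$active],
                                    na.rm = TRUE)), "summary")
      r
    },
    dsi_multicolumn = {
      r <- do.call(run_multi_column_dsi,
                   c(list(params = params), config$args))
      put_csv(data.frame(delta_tau_ms = rep(r$delta_tau,
                                            each = length(r$active) /
                                              length(r$delta_tau)),
                         index_normalised = r$index_normalised_form,
                         index_ratio = r$index_ratio_form), "pooled_indices")
      put_json(list(delta_tau_ms = r$delta_tau), "summary")
      r
    },
    strf = {
      r <- do.call(map_spatiotemporal_rf,
                   c(list(network = build(1L)), config$args))
      put_csv(data.frame(position = rep(r$positions, each = nrow(r$field)),
                         time_s = rep(r$times, times = ncol(r$field)),
                         signed_rate = as.vector(r$field)), "strf")
      put_json(list(tilt_ms_per_deg = r$tilt_ms_per_deg,
                    peak_light = r$peak_light, peak_dark = r$peak_dark),
               "summary")
      r
    },
    phase_scan = {
      r <- do.call(phase_scan, c(list(network = build(1L)), config$args))
      put_csv(data.frame(spatial_phase_deg = r$spatial_phase_deg,
                         f1_amplitude_hz = r$f1_amplitude,
                         f1_phase_rad = r$f1_phase), "phase_scan")
      put_json(list(min_amplitude = min(r$f1_amplitude),
                    spatial_frequency = r$spatial_frequency), "summary")
      r
    },
    modulation = {
      r <- do.call(modulation_ratio,
                   c(list(network = build(3L)), config$args))
      put_csv(data.frame(stage = r$stage, ratio = r$ratio,
                         active = r$active), "modulation_ratios")
      put_json(list(spatial_frequency = r$spatial_frequency), "summary")
      r
    },
    modulation_multicolumn = {
      r <- do.call(run_multi_column_modulation,
                   c(list(params = params), config$args))
      put_csv(data.frame(ratio = r$ratio), "pooled_modulation_ratios")
      put_json(list(spontaneous_rates_hz = r$spontaneous_rates,
                    rectification_onset_contrast =
                      r$rectification_onset_contrast), "summary")
      r
    },
    derivative_checks = {
      r <- list(spatial = spatial_profile_and_derivative_check(
        separation = params$opposite_sign_spacing, radius = params$r_cen),
        temporal = temporal_profile_and_derivative_check(
          params$tau_on, params$tau_off))
      put_json(r, "summary")
      r
    },
    stop("unknown experiment name: ", config$experiment, call. = FALSE)
  )
  cfg_file <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_file)
  files <- c(files, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("v1column")),
    seed = config$seed,
    parameters = unclass(params)[!vapply(unclass(params), is.null,
                                         logical(1))],
    outputs = lapply(files, function(f)
      list(file = basename(f),
           md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(res)
}

#' Model self-checks
#'
#' Runs the package's internal validation battery: agreement between the
#' adaptive and staged integrators and the analytic linear oracle at low
#' contrast, and the spatial and temporal derivative-approximation checks.
#'
#' @param params Model parameters.
#' @return Named list of relative errors (all should be small: below 0.5
#'   percent for the oracle comparisons, below 5 percent for the derivative
#'   approximations).
#' @export
validate_model <- function(params = model_parameters()) {
  net <- build_network(params, cortical_stages = 1, single_cell = TRUE)
  g <- drifting_grating(contrast = 0.01)
  j <- state_index(net, "cortex1", "central")
  oracle <- Mod(analytic_linear_response(net, g)[net$central])
  err <- vapply(c("ode45", "staged"), function(eng) {
    sim <- simulate_network(net, g, 1.5, engine = eng)
    fc <- fourier_components(sim$potentials[, j], sim$times,
                             g$temporal_frequency)
    abs(fc$f1_amplitude - oracle) / oracle
  }, numeric(1))
  list(oracle_rel_error_ode45 = unname(err[1]),
       oracle_rel_error_staged = unname(err[2]),
       spatial_derivative_rel_error = spatial_profile_and_derivative_check(
         separation = params$opposite_sign_spacing, radius = params$r_cen),
       temporal_derivative_rel_error =
         temporal_profile_and_derivative_check(params$tau_on,
                                               params$tau_off))
}
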