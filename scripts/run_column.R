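#!/usr/bin/env Rscript
# Command-line front end for the column model.
#
#   Rscript scripts/run_column.R experiment <preset|name> [options]
#   Rscript scripts/run_column.R simulate [options]
#   Rscript scripts/run_column.R calibrate
#   Rscript scripts/run_column.R validate
#   Rscript scripts/run_column.R list
#
# Options: --config FILE, --out DIR, --seed INT, --grid-spacing DEG,
#          --variant basic|basic_surround|six_channel

suppressPackageStartupMessages({
  library(v1column)
  library(optparse)
})

spec <- list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run-configuration file"),
  make_option("--out", type = "character", default = "v1column-output",
              help = "output directory [%default]"),
  make_option("--seed", type = "integer", default = 1,
              help = "seed for randomised experiments [%default]"),
  make_option("--grid-spacing", type = "double", default = 0.1,
              dest = "grid_spacing",
              help = "cortical grid spacing in degrees [%default]"),
  make_option("--variant", type = "character", default = "basic",
              help = "model variant [%default]")
)
parser <- OptionParser(
  usage = "%prog <simulate|experiment|calibrate|validate|list> [name] [options]",
  option_list = spec)
parsed <- parse_args(parser, positional_arguments = c(0, 2))
verb <- if (length(parsed$args) >= 1) parsed$args[1] else "help"
opt <- parsed$options

quit_usage <- function(msg) {
  message(msg)
  print_help(parser)
  quit(status = 1)
}

switch(
  verb,
  list = {
    cat("Available presets:\n ", paste(names(list_presets()),
                                       collapse = "\n  "), "\n")
  },
  experiment = {
    cfg <- if (!is.null(opt$config)) {
      read_run_config(opt$config)
    } else {
      if (length(parsed$args) < 2) quit_usage("experiment needs a name")
      name <- parsed$args[2]
      if (name %in% names(list_presets()))
        run_config(preset = name, grid_spacing = opt$grid_spacing,
                   seed = opt$seed, out_dir = opt$out)
      else
        run_config(experiment = name, variant = opt$variant,
                   grid_spacing = opt$grid_spacing, seed = opt$seed,
                   out_dir = opt$out)
    }
    run_experiment(cfg)
    cat("outputs written to", cfg$out_dir, "\n")
  },
  simulate = {
    params <- calibrated_parameters(m = if (opt$variant == "six_channel")
      6 else 2)
    net <- build_network(params, cortical_stages = 3,
                         grid_spacing = opt$grid_spacing)
    sim <- simulate_network(net, drifting_grating(), 1.5,
                            engine = "staged")
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(opt$out, "simulation.csv")
    utils::write.csv(
      data.frame(time_s = sim$times,
                 central_stage1_rate_hz =
                   sim$rates[, state_index(net, "cortex1", "central")],
                 central_stage3_rate_hz =
                   sim$rates[, state_index(net, "cortex3", "central")]),
      f, row.names = FALSE)
    cat("wrote", f, "\n")
  },
  calibrate = {
    g <- derive_retinal_geometry(1275, 0.20, 0.49)
    cal <- calibrate_centre_gain()
    p <- model_parameters()
    cat(sprintf("X-cell concentration: %.0f cells/deg^2\n",
                g$x_cell_concentration))
    cat(sprintf("same-sign spacing: %.3f deg, opposite-sign: %.3f deg\n",
                g$same_sign_spacing, g$opposite_sign_spacing))
    cat(sprintf("centre gain: %.1f mV/CU (max rate sensitivity %.0f Hz/CU)\n",
                cal$g_cen, cal$max_rate_sensitivity))
    cat(sprintf("geniculocortical gain: %.3f (2 channels), %.3f (6 channels)\n",
                calibrate_geniculocortical_gain(p),
                calibrate_geniculocortical_gain(model_parameters(m = 6))))
    sp <- calibrate_static_polarisations(p)
    cat(sprintf("static polarisations: sub %.3f, stage1 %.2f mV\n",
                sp$p0_sub, sp$p0_stage1))
  },
  validate = {
    v <- validate_model(calibrated_parameters())
    for (nm in names(v))
      cat(sprintf("%-32s %.3e\n", nm, v[[nm]]))
    ok <- v$oracle_rel_error_staged < 0.005 &&
      v$oracle_rel_error_ode45 < 0.005 &&
      v$spatial_derivative_rel_error < 0.05 &&
      v$temporal_derivative_rel_error < 0.05
    cat(if (ok) "all checks passed\n" else "CHECKS FAILED\n")
    quit(status = if (ok) 0 else 1)
  },
  quit_usage(paste("unknown command:", verb))
)
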