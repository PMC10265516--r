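#!/usr/bin/env Rscript
# Command-line front end over the liflux package.
#
#   Rscript scripts/liflux.R simulate      --config cfg.json --out traj.csv
#   Rscript scripts/liflux.R dose-response --config cfg.json --out dose.csv
#   Rscript scripts/liflux.R ph-scan       --config cfg.json --out ph.csv
#   Rscript scripts/liflux.R na-scan       --config cfg.json --out na.csv
#   Rscript scripts/liflux.R synth --kind kinetics|dose|ph --seed 1 --out x.csv
#   Rscript scripts/liflux.R fit --mode mm|mwc --data x.csv --out fit.json
#   Rscript scripts/liflux.R calibrate --out bundle.json
#
# The configuration file (JSON or YAML) may hold `cell`, `membrane` and
# `exchanger` blocks; see ?read_run_config. Omitted blocks use the
# calibrated package defaults.

suppressMessages(library(liflux))
suppressMessages(library(optparse))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L)
  stop("usage: liflux.R <simulate|dose-response|ph-scan|na-scan|synth|fit|calibrate> [options]")
cmd <- argv[1L]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "out.csv"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--kind", type = "character", default = "kinetics"),
  make_option("--mode", type = "character", default = "mm"),
  make_option("--data", type = "character", default = NULL),
  make_option("--t-end", type = "double", default = 60),
  make_option("--times", type = "character", default = "0,5,10,20,30,60"),
  make_option("--log-level", type = "character", default = "info")
)), args = argv[-1L])

run <- if (!is.null(opts$config)) read_run_config(opts$config) else
  list(cell = cell_config(), membrane = membrane_params(),
       exchanger = exchanger_params())
quiet <- identical(opts$`log-level`, "quiet")
say <- function(...) if (!quiet) message(...)

write_out <- function(df) {
  utils::write.csv(df, opts$out, row.names = FALSE)
  say("wrote ", opts$out, " (", nrow(df), " rows)")
}

if (cmd == "simulate") {
  times <- as.numeric(strsplit(opts$times, ",")[[1]])
  tr <- simulate_uptake(run$cell, run$membrane, run$exchanger, times = times)
  write_out(tr[, c("t_s", "Li_cell_mM", "delta7Li_permil", "pH_in", "Vm_mV")])
} else if (cmd == "dose-response") {
  write_out(dose_response(run$cell, run$membrane, run$exchanger,
                          t_end = opts$`t-end`))
} else if (cmd == "ph-scan") {
  write_out(ph_scan(run$cell, run$membrane, run$exchanger,
                    t_end = opts$`t-end`))
} else if (cmd == "na-scan") {
  write_out(na_scan(run$cell, run$membrane, run$exchanger,
                    t_end = opts$`t-end`))
} else if (cmd == "synth") {
  ns <- noise_spec(seed = opts$seed)
  tab <- switch(opts$kind,
    kinetics = generate_kinetics(run$cell, run$membrane, run$exchanger,
                                 noise = ns),
    dose = generate_dose_response(run$cell, run$membrane, run$exchanger,
                                  noise = ns),
    ph = generate_ph_scan(run$cell, run$membrane, run$exchanger, noise = ns),
    stop("--kind must be kinetics, dose or ph"))
  write_out(tab)
} else if (cmd == "fit") {
  if (is.null(opts$data)) stop("fit needs --data <csv>")
  tab <- utils::read.csv(opts$data)
  fit <- switch(opts$mode,
    mm = fit_mm(tab$Li_out_mM, tab$Li_cell_mM),
    mwc = fit_mwc(tab$pH_in0, tab$Li_cell_mM),
    stop("--mode must be mm or mwc (joint fits: use liflux::joint_fit)"))
  jsonlite::write_json(list(estimates = as.list(fit$estimates),
                            se = as.list(fit$se), r2 = fit$r2,
                            converged = fit$converged,
                            iterations = fit$iterations),
                       opts$out, auto_unbox = TRUE, digits = NA)
  say("wrote ", opts$out)
} else if (cmd == "calibrate") {
  b <- calibrate_defaults(verbose = !quiet)
  bundle_to_json(b, opts$out)
  say("wrote ", opts$out)
} else {
  stop("unknown command: ", cmd)
}
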