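#!/usr/bin/env Rscript
# Thin command-line wrapper over robustgen::run_pipeline(): simulates a
# multi-environment breeding program and fits both robustness models.
# Usage:
#   Rscript scripts/pipeline.R --out results/run1 [--seed 1]
#     [--preset test|paper] [--config cfg.yaml] [--trend] [--desk-guard]
# A YAML config, when given, overrides sim_config() fields by name.
suppressPackageStartupMessages(library(robustgen))
suppressPackageStartupMessages(library(optparse))

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", help = "output directory"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--preset", type = "character", default = NULL,
              help = "mcmc preset: test or paper"),
  make_option("--config", type = "character", default = NULL,
              help = "YAML file with sim_config() overrides"),
  make_option("--trend", action = "store_true", default = FALSE,
              help = "also fit the per-generation rg trend"),
  make_option("--desk-guard", action = "store_true", default = FALSE,
              dest = "desk_guard", help = "refuse production-length presets")
)))

if (is.null(opts$out)) {
  message("error: --out is required")
  quit(status = 1L)
}

status <- tryCatch({
  cfg_args <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
  if (!is.null(cfg_args$rg)) cfg_args$rg <- as.matrix(do.call(rbind, cfg_args$rg))
  cfg <- do.call(sim_config, cfg_args)
  run_pipeline(cfg, out_dir = opts$out, seed = opts$seed,
               preset = opts$preset, desk_guard = opts$desk_guard,
               trend = opts$trend)
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  if (grepl("desk_guard|required|--", conditionMessage(e))) 1L else 2L
})
quit(status = status)
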