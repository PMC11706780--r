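#!/usr/bin/env Rscript
# Thin command-line wrapper over axonpearl::run_experiment():
#   Rscript scripts/run_pipeline.R --config run.yaml [--seed 1] [--out dir]
# Runs the configured generate -> measure -> relax -> predict stages and
# prints the report.

suppressMessages({
  library(optparse)
  library(axonpearl)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--seed", type = "integer", default = NA_integer_),
  make_option("--out", type = "character", default = NA_character_)
)))

if (is.null(opts$config) || is.na(opts$config))
  stop("--config is required", call. = FALSE)
cfg <- read_run_config(opts$config)
if (!is.na(opts$seed)) cfg$seed <- opts$seed
if (!is.na(opts$out)) cfg$output <- opts$out

manifest <- run_experiment(cfg)
print(manifest)
cat("\n")
report_manifest(manifest)
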