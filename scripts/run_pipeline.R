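#!/usr/bin/env Rscript
# Thin CLI over mlxtools::run_pipeline().
#   Rscript scripts/run_pipeline.R --config cfg.yaml --out DIR --seed N
# Omit --config to use the package defaults.

suppressPackageStartupMessages({
  library(optparse)
  library(mlxtools)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML pipeline config (default: package defaults)"),
  make_option("--out", type = "character", default = "pipeline_out",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = 1,
              help = "seed for every stochastic stage [default %default]")
)))

cfg <- if (is.null(opts$config)) default_pipeline_config(opts$seed) else {
  c0 <- yaml::read_yaml(opts$config)
  c0$seed <- opts$seed
  c0
}
report <- run_pipeline(cfg, out_dir = opts$out)
print(report)
message("outputs written to ", opts$out)
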