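#!/usr/bin/env Rscript
# Thin CLI over mlxtools::run_mlx_simulation().
#   Rscript scripts/simulate_mlx.R --mode MLX --generations 20 \
#     --out trajectory.csv --seed 1

suppressPackageStartupMessages({
  library(optparse)
  library(mlxtools)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--L", type = "integer", default = 20),
  make_option("--s-male", type = "double", default = 0.05, dest = "s_male"),
  make_option("--s-female", type = "double", default = 0.05,
              dest = "s_female"),
  make_option("--init-freq", type = "double", default = 0.5,
              dest = "init_freq"),
  make_option("--n-main", type = "integer", default = 640, dest = "n_main"),
  make_option("--n-rb", type = "integer", default = 32, dest = "n_rb"),
  make_option("--migrants", type = "integer", default = 32),
  make_option("--generations", type = "integer", default = 20),
  make_option("--mode", type = "character", default = "MLX"),
  make_option("--out", type = "character", default = "trajectory.csv"),
  make_option("--seed", type = "integer", default = 1)
)))

tr <- run_mlx_simulation(
  L = opts$L, s_male = opts$s_male, s_female = opts$s_female,
  init_freq = opts$init_freq, n_main = opts$n_main, n_rb = opts$n_rb,
  migrants_per_gen = opts$migrants, generations = opts$generations,
  mode = opts$mode, seed = opts$seed
)
readr::write_csv(tibble::as_tibble(tr), opts$out)
message("trajectory written to ", opts$out)
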