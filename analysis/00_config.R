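# Shared settings for the analysis workflow. Every numbered script
# sources this file, so the whole analysis is reproducible from one seed
# and one scenario definition.
#
# Run the scripts in order from the repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_assess_indices.R
#   Rscript analysis/03_spatial_coupling.R
#   Rscript analysis/04_drivers.R
# An optional --seed <int> argument overrides the default seed.

library(ecocoupling)

parse_seed <- function(default = 1L) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i) == 1 && length(args) >= i + 1)
    as.integer(args[i + 1]) else default
}

analysis_seed <- parse_seed()

# study conditions: a 100 x 100 cell landscape (1 km cells in spirit),
# two annual snapshots, human pressure negatively coupled (-0.8) to
# ecological condition, 10 x 10 cell analysis units
analysis_config <- function(seed = analysis_seed, unit_cells = 10,
                            n_perm = 999, ...) {
  run_config(scenario = scenario_preset("negative_coupling", seed = seed),
             unit_cells = unit_cells, n_perm = n_perm, seed = seed, ...)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

say <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...))
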