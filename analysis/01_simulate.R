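#!/usr/bin/env Rscript
# Stage 1: generate the synthetic landmark study.
#
# Emits a TPS + metadata + Newick bundle under the default study design
# (18 species, 6 per parasitic mode; 7 individuals per species; 30
# specimens digitised twice), plus the three reduced fixture bundles
# (null / mode-effect / phylo-signal) used for calibration checks.

library(hookmorph)

out_dir <- "results/data"
seed <- 1L

sim <- simulate_dataset(simulation_spec(seed = seed),
                        dir = file.path(out_dir, "main"))
cat("main bundle:", n_configs(sim$dataset), "digitisations of",
    length(sim$truth$species), "species ->", file.path(out_dir, "main"),
    "\n")
cat("modes:", paste(capture.output(table(sim$dataset$meta$mode[
  sim$dataset$meta$replicate_id == 1])), collapse = " "), "\n")

dirs <- make_fixtures(file.path(out_dir, "fixtures"), seed = seed)
cat("fixture bundles:", paste(names(dirs), collapse = ", "), "->",
    file.path(out_dir, "fixtures"), "\n")
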