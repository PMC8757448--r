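#!/usr/bin/env Rscript
# Grid-search recovery of the Langmuir kinetic constants from synthetic
# fluid-phase measurements: generates adsorption + desorption series at the
# fitted constants with triplicate 5% CV noise, then fits (k_a, k_d) by
# exhaustive search on the 20 x 20 grid, deriving the capacity from the
# adsorption endpoints at every candidate.
#
# Usage: Rscript analysis/02_fit_protein.R [seed]

suppressPackageStartupMessages(library(sorbcell))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

out_dir <- file.path("results", "protein_fit")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- read_run_config(system.file("extdata", "default_config.yaml",
                                   package = "sorbcell"))
p_true <- cfg$protein
g <- cfg$geometry

# one shared forward model (the fit's discretisation) for generation and
# fitting, so the comparison probes statistical recovery, not grid error
ads <- generate_protein_series(
  p_true, g, "adsorption",
  noise = noise_spec(magnitude = cfg$noise$magnitude,
                     replicates = cfg$noise$replicates, seed = seed),
  mix_at_sampling = TRUE, nz = 80, dt = 0.05)
cs_end <- utils::tail(attr(ads, "trajectory")$c_surface, 1)
des <- generate_protein_series(
  p_true, g, "desorption",
  noise = noise_spec(magnitude = cfg$noise$magnitude,
                     replicates = cfg$noise$replicates, seed = seed + 1000),
  initial_surface = cs_end, mix_at_sampling = TRUE, nz = 80, dt = 0.05)
write_measurement_csv(ads, file.path(out_dir, "adsorption_series.csv"))
write_measurement_csv(des, file.path(out_dir, "desorption_series.csv"))

fit <- grid_fit_protein(ads, des, initial_fluid = 9500, geometry = g,
                        mix_at_sampling = TRUE)
utils::write.csv(fit$surface, file.path(out_dir, "error_surface.csv"),
                 row.names = FALSE)
write_summary_json(list(
  seed = seed,
  k_a_fit = fit$k_a, k_d_fit = fit$k_d, c_s_max_fit = fit$c_s_max,
  k_a_true = p_true$k_a, k_d_true = p_true$k_d,
  equilibrium_ratio_fit = fit$k_d / fit$k_a,
  equilibrium_ratio_true = p_true$k_d / p_true$k_a,
  error_percent = fit$error),
  file.path(out_dir, "fit.json"))

cat(sprintf("true (k_a, k_d) = (%.3g, %.3g); fitted (%.3g, %.3g), error %.2f%%\n",
            p_true$k_a, p_true$k_d, fit$k_a, fit$k_d, fit$error))
cat(sprintf("equilibrium ratio k_d/k_a: true %.1f, fitted %.1f; capacity %.2f ug/mm^2 (true %.1f)\n",
            p_true$k_d / p_true$k_a, fit$k_d / fit$k_a, fit$c_s_max,
            p_true$c_s_max))
cat("note: the absolute kinetic scale sits on a flat diagonal error valley\n",
    "(transport-limited design); the ratio and capacity are the reliably\n",
    "identified quantities under replicate noise.\n")
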