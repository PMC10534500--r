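#!/usr/bin/env Rscript

# Step 2 — preprocessing and CLS unmixing.
#
# Renders one tablet per modality, applies the modality recipe (Raman:
# SG smoothing -> Whittaker/AsLS baseline -> area normalization; NIR: SG
# first derivative), unmixes against the identically treated pure library
# and compares the recovered HPMC concentration map with the generator's
# ground truth.

suppressPackageStartupMessages(library(dissmap))
dir.create("results", showWarnings = FALSE)
seed <- 1

d <- experiment_designs()[["DR16"]] # 20% HPMC, 100-150 um
for (m in c("raman", "nir")) {
  lib <- generate_pure_spectra(m, seed = derive_seed(seed, 1))
  geom <- map_geometry(m)
  pm <- generate_particle_map(d, geom$grid_shape, geom$pixel_pitch,
                              seed = derive_seed(seed, 2))
  cube <- render_cube(pm, lib, noise_sd = 0.02,
                      baseline_amplitude = if (m == "raman") 2 else 0.2,
                      seed = derive_seed(seed, 3))
  op <- fit_cls(preprocess_modality(lib, m))
  cm <- concentration_map(op, preprocess_modality(cube, m), "HPMC")
  truth <- 100 * pm$fractions[, , "HPMC"]
  fit <- lm(as.numeric(cm$values) ~ as.numeric(truth))
  cat(sprintf("%-5s %dx%d map: mean HPMC %.2f%% (truth %.2f%%), pixel slope %.3f, R2 %.4f, cond %.1f\n",
              m, nrow(cm$values), ncol(cm$values), mean_concentration(cm),
              mean(truth), coef(fit)[2], summary(fit)$r.squared,
              op$condition_number))
  write.csv(cm$values, sprintf("results/conc_map_%s_DR16.csv", m),
            row.names = FALSE)
}
cat("Concentration maps written to results/conc_map_<modality>_DR16.csv\n")
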