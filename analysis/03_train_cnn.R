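#!/usr/bin/env Rscript

# Step 3 — particle-size CNN.
#
# Trains the convolutional regressor on ground-truth HPMC concentration maps
# of the 112 calibration tablets (96 train / 16 validation, stratified) at
# the Raman geometry and evaluates it on the 32 validation-formulation
# tablets. Writes the training history and the per-tablet predictions.

suppressPackageStartupMessages(library(dissmap))
dir.create("results", showWarnings = FALSE)
master <- 1

designs <- experiment_designs()
maps <- list(); labels <- numeric(0); role <- character(0); strata <- NULL
idx <- 0
for (d in designs) for (r in 1:4) {
  idx <- idx + 1
  pm <- generate_particle_map(d, c(31, 31), 40,
                              seed = derive_seed(master, idx))
  maps[[idx]] <- 100 * pm$fractions[, , "HPMC"]
  labels[idx] <- sieve_upper(d$size_fraction)
  role[idx] <- d$role
  if (d$role == "calibration")
    strata <- rbind(strata, data.frame(conc = d$hpmc_frac,
                                       size = d$size_fraction))
}
cal <- which(role == "calibration"); val <- which(role == "validation")
sp <- split_train_val(strata, 16, seed = derive_seed(master, 902))

cnn <- build_particle_cnn(c(31, 31), seed = derive_seed(master, 900))
cat(sprintf("CNN: %d trainable parameters, input 31x31\n",
            cnn_param_count(cnn)))
cnn <- train_particle_cnn(cnn, maps[cal[sp$train]], labels[cal[sp$train]],
                          maps[cal[sp$val]], labels[cal[sp$val]],
                          cfg = cnn_train_config(seed = derive_seed(master,
                                                                    901)))
write.csv(cnn$history, "results/cnn_history.csv", row.names = FALSE)

pred <- predict_size(cnn, maps[val])
out <- data.frame(true_um = labels[val], predicted_um = round(pred, 2))
write.csv(out, "results/cnn_size_predictions.csv", row.names = FALSE)
cat(sprintf("Held-out (32 validation tablets): MAE %.2f um, rank correlation %.3f\n",
            mean(abs(pred - labels[val])),
            cor(pred, labels[val], method = "spearman")))
print(round(tapply(pred, labels[val], mean), 1))
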