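# Shared fixtures, built in code.

# A small hand-made particle map with known per-pixel fractions, bypassing
# the disk placer; used to test the linear mixing model directly.
manual_particle_map <- function(hpmc_px, design, pixel_pitch = 40) {
  H <- nrow(hpmc_px)
  W <- ncol(hpmc_px)
  bg <- c(DR = design$dr_frac, MCC = design$mcc_frac,
          lactose = design$lactose_frac, MgSt = design$mgst_frac)
  bg <- bg / sum(bg)
  fractions <- array(0, c(H, W, 5),
                     dimnames = list(NULL, NULL,
                                     c("DR", "HPMC", "MCC", "lactose",
                                       "MgSt")))
  fractions[, , "HPMC"] <- hpmc_px
  for (nm in names(bg)) fractions[, , nm] <- (1 - hpmc_px) * bg[[nm]]
  structure(list(fractions = fractions, pixel_pitch = pixel_pitch,
                 particles = data.frame(x = numeric(0), y = numeric(0),
                                        diameter = numeric(0)),
                 realized_fraction = mean(hpmc_px), design = design,
                 seed = NA_integer_),
            class = "particle_map")
}

# Ground-truth concentration maps + size labels for all 36 formulations x
# `replicates` tablets at the given geometry (no spectra rendered).
make_size_benchmark <- function(master, grid_shape, pixel_pitch,
                                replicates = 4) {
  designs <- experiment_designs()
  maps <- list()
  labels <- numeric(0)
  role <- character(0)
  strata <- NULL
  idx <- 0
  for (d in designs) {
    for (r in seq_len(replicates)) {
      idx <- idx + 1
      jd <- dissmap:::jitter_design(d, 0.01, seed = derive_seed(master,
                                                               idx * 3))
      pm <- generate_particle_map(jd, grid_shape, pixel_pitch,
                                  seed = derive_seed(master, idx * 3 + 1))
      maps[[idx]] <- 100 * pm$fractions[, , "HPMC"]
      labels[idx] <- sieve_upper(d$size_fraction)
      role[idx] <- d$role
      if (d$role == "calibration") {
        strata <- rbind(strata, data.frame(conc = d$hpmc_frac,
                                           size = d$size_fraction))
      }
    }
  }
  list(maps = maps, labels = labels, strata = strata,
       cal = which(role == "calibration"), val = which(role == "validation"))
}

# Ground-truth (concentration, size) inputs and noise-free profiles for the
# ANN parameter-recovery benchmark.
make_gt_ann_data <- function(replicates = 4) {
  designs <- experiment_designs()
  Xtr <- NULL; Ytr <- NULL; Xval <- NULL; val_profiles <- list()
  for (d in designs) {
    for (r in seq_len(replicates)) {
      x <- c(100 * d$hpmc_frac, sieve_upper(d$size_fraction))
      pr <- simulate_dissolution(d, noise_sd = 0)
      if (d$role == "calibration") {
        Xtr <- rbind(Xtr, x)
        Ytr <- rbind(Ytr, pr$released)
      } else {
        Xval <- rbind(Xval, x)
        val_profiles <- c(val_profiles, list(pr))
      }
    }
  }
  list(Xtr = Xtr, Ytr = Ytr, Xval = Xval, val_profiles = val_profiles)
}
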