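#' Experiment configuration
#'
#' Collects every tunable of the end-to-end pipeline: which imaging
#' modalities to run, how many replicate tablets per formulation, spectral
#' dimensions and noise of the synthetic instrument, preprocessing settings,
#' CNN and ANN training settings, and the master seed from which all
#' randomness derives. The ANN ensemble default (`runs = 10`) is the
#' desk-scale setting; set `runs = 100` for the full-scale selection.
#'
#' @param modalities character subset of `c("raman", "nir")`.
#' @param replicates tablets per formulation (default 4).
#' @param master_seed integer master seed.
#' @param n_bands,noise_sd,baseline_amplitude,similarity_target named
#'   per-modality synthetic-instrument settings.
#' @param profile_noise_sd dissolution measurement noise (%).
#' @param jitter_sd relative tablet-to-tablet composition jitter.
#' @param cnn list: `filters`, `dropout_rate`, `fc_units`, `n_val` (CNN
#'   validation tablets), `train` ([cnn_train_config()]).
#' @param ann list: `runs`, `hidden_range`, `max_epochs`, `grad_tol`.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(modalities = c("raman", "nir"),
                              replicates = 4, master_seed = 1,
                              n_bands = c(raman = 300, nir = 220),
                              noise_sd = c(raman = 0.02, nir = 0.02),
                              baseline_amplitude = c(raman = 2, nir = 0.2),
                              similarity_target = c(raman = 0.6, nir = 0.92),
                              profile_noise_sd = 1, jitter_sd = 0.01,
                              cnn = list(), ann = list()) {
  if (length(modalities) == 0) {
    stop("invalid-configuration: at least one modality is required",
         call. = FALSE)
  }
  modalities <- match.arg(modalities, c("raman", "nir"), several.ok = TRUE)
  stopifnot(replicates >= 1)
  cnn_defaults <- list(filters = c(16, 16), dropout_rate = 0.2,
                       fc_units = 32, pool = 4, n_val = 16,
                       train = cnn_train_config())
  cnn <- utils::modifyList(cnn_defaults, cnn)
  ann_defaults <- list(runs = 10, hidden_range = 1:10, max_epochs = 100,
                       grad_tol = 1e-7)
  ann <- utils::modifyList(ann_defaults, ann)
  structure(list(modalities = modalities, replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed), n_bands = n_bands,
                 noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 similarity_target = similarity_target,
                 profile_noise_sd = profile_noise_sd, jitter_sd = jitter_sd,
                 cnn = cnn, ann = ann),
            class = "experiment_config")
}

# Short provenance hash of the configuration (rolling polynomial hash of its
# JSON serialization); embedded in every report.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 12,
                        force = TRUE)
  b <- utf8ToInt(as.character(s))
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full imaging-to-dissolution experiment
#'
#' For each modality: synthesize the 36-formulation design at `replicates`
#' tablets each; render and preprocess the hyperspectral maps; CLS-unmix
#' them into HPMC concentration maps; extract the mean HPMC concentration
#' and train the particle-size CNN on the calibration tablets (with an
#' internal train/validation split); train the Bayesian-regularized ANN
#' ensemble on (mean concentration, CNN size) -> 37-point profile; predict
#' the validation tablets and score them with f2 (85% truncation), RMSE and
#' R squared. Deterministic given the configuration and master seed.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print stage progress.
#' @return an `experiment_report` (see [compare_modalities()],
#'   [write_report()]).
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  designs <- experiment_designs()
  roles <- vapply(designs, `[[`, character(1), "role")
  n_designs <- length(designs)
  reps <- cfg$replicates
  master <- cfg$master_seed
  say <- function(...) if (verbose) message(sprintf(...))

  # Record plan shared across modalities: tablet-level seeds, jittered
  # compositions and measured profiles are modality-independent.
  plan <- list()
  idx <- 0L
  for (d in designs) {
    for (rep_i in seq_len(reps)) {
      idx <- idx + 1L
      rec_seed <- derive_seed(master, 100 + idx)
      jd <- jitter_design(d, cfg$jitter_sd, seed = derive_seed(rec_seed, 1))
      plan[[idx]] <- list(
        id = sprintf("%s_r%d", d$name, rep_i), design = jd,
        nominal = d, replicate = rep_i, seed = rec_seed,
        profile = simulate_dissolution(jd, noise_sd = cfg$profile_noise_sd,
                                       seed = derive_seed(rec_seed, 2)))
    }
  }
  is_cal <- rep(roles == "calibration", each = reps)

  per_modality <- list()
  for (mi in seq_along(cfg$modalities)) {
    m <- cfg$modalities[mi]
    say("[%s] generating library and CLS operator", m)
    lib <- generate_pure_spectra(m, cfg$n_bands[[m]],
                                 cfg$similarity_target[[m]],
                                 seed = derive_seed(master, mi))
    lib_pp <- preprocess_modality(lib, m)
    op <- fit_cls(lib_pp)
    geom <- map_geometry(m)

    say("[%s] rendering and unmixing %d tablets", m, length(plan))
    maps <- vector("list", length(plan))
    cls_mean <- numeric(length(plan))
    for (i in seq_along(plan)) {
      p <- plan[[i]]
      pm <- generate_particle_map(p$design, geom$grid_shape,
                                  geom$pixel_pitch,
                                  seed = derive_seed(p$seed, mi + 2))
      cube <- render_cube(pm, lib, noise_sd = cfg$noise_sd[[m]],
                          baseline_amplitude = cfg$baseline_amplitude[[m]],
                          seed = derive_seed(p$seed, mi + 10))
      cube_pp <- preprocess_modality(cube, m)
      cm <- concentration_map(op, cube_pp, "HPMC")
      maps[[i]] <- cm$values
      cls_mean[i] <- mean_concentration(cm)
    }

    true_conc <- vapply(plan, function(p) 100 * p$design$hpmc_frac,
                        numeric(1))
    true_size <- vapply(plan, function(p) sieve_upper(p$design$size_fraction),
                        numeric(1))

    say("[%s] training particle-size CNN", m)
    cal_idx <- which(is_cal)
    strata <- data.frame(
      conc = vapply(plan[cal_idx], function(p) p$nominal$hpmc_frac,
                    numeric(1)),
      size = vapply(plan[cal_idx], function(p) p$nominal$size_fraction,
                    character(1)))
    sp <- split_train_val(strata, cfg$cnn$n_val,
                          seed = derive_seed(master, 600 + mi))
    cnn_cfg <- cfg$cnn$train
    cnn_cfg$seed <- derive_seed(master, 500 + mi)
    cnn <- build_particle_cnn(geom$grid_shape, filters = cfg$cnn$filters,
                              dropout_rate = cfg$cnn$dropout_rate,
                              fc_units = cfg$cnn$fc_units,
                              pool = cfg$cnn$pool,
                              seed = derive_seed(master, 400 + mi))
    cnn <- train_particle_cnn(
      cnn, maps[cal_idx[sp$train]], true_size[cal_idx[sp$train]],
      maps[cal_idx[sp$val]], true_size[cal_idx[sp$val]], cnn_cfg)
    size_pred <- predict_size(cnn, maps)

    say("[%s] training dissolution ANN ensemble", m)
    val_idx <- which(!is_cal)
    Xtr <- cbind(cls_mean[cal_idx], size_pred[cal_idx])
    Ytr <- do.call(rbind, lapply(plan[cal_idx],
                                 function(p) p$profile$released))
    Xval <- cbind(cls_mean[val_idx], size_pred[val_idx])
    val_profiles <- lapply(plan[val_idx], `[[`, "profile")
    sel <- train_ensemble(Xtr, Ytr, Xval, val_profiles,
                          runs = cfg$ann$runs,
                          hidden_range = cfg$ann$hidden_range,
                          master_seed = derive_seed(master, 700 + mi),
                          max_epochs = cfg$ann$max_epochs,
                          grad_tol = cfg$ann$grad_tol)

    say("[%s] evaluating validation formulations", m)
    rec_metrics <- lapply(seq_along(val_idx), function(k) {
      i <- val_idx[k]
      pred <- predict_profile(sel$best_model, cls_mean[i], size_pred[i])
      mt <- profile_metrics(plan[[i]]$profile, pred)
      list(id = plan[[i]]$id, formulation = plan[[i]]$nominal$name,
           replicate = plan[[i]]$replicate,
           true_profile = plan[[i]]$profile$released,
           predicted_profile = pred$released,
           f2 = mt$f2, rmse = mt$rmse, r2 = mt$r2)
    })
    forms <- unique(vapply(rec_metrics, `[[`, character(1), "formulation"))
    formulations <- lapply(forms, function(fn) {
      sub <- Filter(function(r) r$formulation == fn, rec_metrics)
      list(name = fn,
           f2 = mean(vapply(sub, `[[`, numeric(1), "f2")),
           rmse = mean(vapply(sub, `[[`, numeric(1), "rmse")),
           r2 = mean(vapply(sub, `[[`, numeric(1), "r2")))
    })
    shift <- mean(true_conc[val_idx]) - mean(cls_mean[val_idx])
    per_modality[[m]] <- list(
      mean_f2 = mean(vapply(rec_metrics, `[[`, numeric(1), "f2")),
      mean_rmse = mean(vapply(rec_metrics, `[[`, numeric(1), "rmse")),
      mean_r2 = mean(vapply(rec_metrics, `[[`, numeric(1), "r2")),
      selected_n_hidden = sel$best_n_hidden,
      selected_run = sel$best_run,
      selection_score = sel$best_score,
      cls_condition_number = op$condition_number,
      concentration_shift = shift,
      concentration = list(id = vapply(plan, `[[`, character(1), "id"),
                           true_pct = true_conc, cls_mean_pct = cls_mean,
                           shifted_pct = mean_shift_correction(
                             cls_mean, true_conc)),
      size = list(id = vapply(plan, `[[`, character(1), "id"),
                  true_um = true_size, predicted_um = size_pred),
      cnn_val_mae = mean(abs(size_pred[cal_idx[sp$val]] -
                               true_size[cal_idx[sp$val]])),
      score_table = sel$scores,
      formulations = formulations,
      validation_records = rec_metrics)
  }

  structure(list(
    config_hash = config_hash(cfg), master_seed = master,
    modalities = cfg$modalities, replicates = reps,
    times = dissolution_times(), per_modality = per_modality
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> seed %d, config %s\n", x$master_seed,
              x$config_hash))
  for (m in names(x$per_modality)) {
    pm <- x$per_modality[[m]]
    cat(sprintf("  %-5s mean f2 %.1f, RMSE %.2f, R2 %.3f (ANN: %d hidden)\n",
                m, pm$mean_f2, pm$mean_rmse, pm$mean_r2,
                pm$selected_n_hidden))
  }
  invisible(x)
}

#' Compare the modalities of an experiment report
#'
#' Side-by-side f2 / RMSE / R squared per validation formulation, per-metric
#' means, and f2 win counts (a tie contributes 0.5 to each side).
#'
#' @param report an [run_experiment()] report with at least two modalities.
#' @return a `modality_comparison`: `table` (per-formulation data frame),
#'   `wins` (named win counts by f2), `means` (per-modality metric means).
#' @export
compare_modalities <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  mods <- names(report$per_modality)
  if (length(mods) < 2) {
    stop("not-comparable: the report contains fewer than two modalities",
         call. = FALSE)
  }
  forms <- vapply(report$per_modality[[1]]$formulations, `[[`,
                  character(1), "name")
  tab <- data.frame(formulation = forms)
  for (m in mods) {
    fl <- report$per_modality[[m]]$formulations
    stopifnot(identical(vapply(fl, `[[`, character(1), "name"), forms))
    tab[[paste0("f2_", m)]] <- vapply(fl, `[[`, numeric(1), "f2")
    tab[[paste0("rmse_", m)]] <- vapply(fl, `[[`, numeric(1), "rmse")
    tab[[paste0("r2_", m)]] <- vapply(fl, `[[`, numeric(1), "r2")
  }
  wins <- stats::setNames(numeric(length(mods)), mods)
  if (length(mods) == 2) {
    a <- tab[[paste0("f2_", mods[1])]]
    b <- tab[[paste0("f2_", mods[2])]]
    wins[mods[1]] <- sum(a > b) + 0.5 * sum(a == b)
    wins[mods[2]] <- sum(b > a) + 0.5 * sum(a == b)
  }
  means <- lapply(report$per_modality, function(pm)
    c(f2 = pm$mean_f2, rmse = pm$mean_rmse, r2 = pm$mean_r2))
  structure(list(table = tab, wins = wins, means = means),
            class = "modality_comparison")
}

#' @export
print.modality_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  cat("f2 wins:", paste(names(x$wins), format(x$wins), collapse = ", "),
      "\n")
  invisible(x)
}
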