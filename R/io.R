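# Plain-text persistence: dissolution profiles and score tables as CSV,
# reports as JSON, datasets as a directory-per-record tree of CSV + JSON
# (an HDF5-like hierarchy in portable text form).

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a dissolution profile as CSV
#'
#' Two columns (`time_min`, `released_pct`), full double precision, so a
#' write-read roundtrip preserves every point exactly.
#'
#' @param profile a [dissolution_profile()].
#' @param path file path.
#' @return `read_profile_csv()` returns the profile; `write_profile_csv()`
#'   its path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "dissolution_profile"))
  df <- data.frame(time_min = fmt_num(profile$times),
                   released_pct = fmt_num(profile$released))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, colClasses = "character"),
                 error = function(e) {
                   stop("parse error in profile CSV ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (!identical(names(df), c("time_min", "released_pct"))) {
    stop("parse error in profile CSV ", path,
         ": expected columns time_min, released_pct", call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(df$time_min))
  rl <- suppressWarnings(as.numeric(df$released_pct))
  if (nrow(df) == 0 || anyNA(tm) || anyNA(rl)) {
    stop("parse error in profile CSV ", path, ": non-numeric or missing values",
         call. = FALSE)
  }
  dissolution_profile(tm, rl)
}

write_matrix_csv <- function(m, path) {
  ch <- matrix(fmt_num(m), nrow(m), ncol(m))
  utils::write.table(ch, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path, nrow_expected = NULL,
                            ncol_expected = NULL) {
  m <- tryCatch(as.matrix(read.csv(path, header = FALSE,
                                   colClasses = "numeric")),
                error = function(e) {
                  stop("parse error in ", path, ": ", conditionMessage(e),
                       call. = FALSE)
                })
  if ((!is.null(nrow_expected) && nrow(m) != nrow_expected) ||
      (!is.null(ncol_expected) && ncol(m) != ncol_expected)) {
    stop("parse error in ", path, ": unexpected shape ", nrow(m), "x",
         ncol(m), call. = FALSE)
  }
  dimnames(m) <- NULL
  m
}

#' Persist a synthetic dataset as a directory tree
#'
#' Layout: `<dir>/designs.csv` plus one `records/<id>/` directory per record
#' holding `metadata.json` (design, seeds, geometry, band axes),
#' `profile.csv`, and per modality `fractions_<m>.csv` (pixels x components)
#' and `cube_<m>.csv` (pixels x bands). Everything is plain text at full
#' double precision, so `read_dataset()` reproduces equal arrays.
#'
#' @param records a [generate_dataset()] result.
#' @param dir target directory (created if missing).
#' @return `dir`, invisibly; `read_dataset()` returns the records list.
#' @export
write_dataset <- function(records, dir) {
  dir.create(file.path(dir, "records"), recursive = TRUE,
             showWarnings = FALSE)
  summ <- data.frame(
    id = names(records),
    name = vapply(records, function(r) r$design$name, character(1)),
    replicate = vapply(records, function(r) r$replicate, integer(1)),
    hpmc_pct = vapply(records, function(r) 100 * r$design$hpmc_frac,
                      numeric(1)),
    size_fraction = vapply(records, function(r) r$design$size_fraction,
                           character(1)),
    role = vapply(records, function(r) r$design$role, character(1)))
  write.csv(summ, file.path(dir, "designs.csv"), row.names = FALSE)
  for (id in names(records)) {
    r <- records[[id]]
    rd <- file.path(dir, "records", id)
    dir.create(rd, showWarnings = FALSE)
    meta <- list(id = id, replicate = r$replicate, seed = r$seed,
                 design = unclass(r$design), modalities = list())
    write_profile_csv(r$profile, file.path(rd, "profile.csv"))
    for (m in c("raman", "nir")) {
      pm <- r[[paste0("map_", m)]]
      if (is.null(pm)) next
      d <- dim(pm$fractions)
      meta$modalities[[m]] <- list(H = d[1], W = d[2],
                                   pixel_pitch = pm$pixel_pitch,
                                   n_particles = nrow(pm$particles))
      write_matrix_csv(matrix(pm$fractions, d[1] * d[2], d[3]),
                       file.path(rd, paste0("fractions_", m, ".csv")))
      cube <- r[[paste0("cube_", m)]]
      if (!is.null(cube)) {
        dc <- dim(cube$values)
        meta$modalities[[m]]$n_bands <- dc[3]
        write_matrix_csv(matrix(cube$values, dc[1] * dc[2], dc[3]),
                         file.path(rd, paste0("cube_", m, ".csv")))
      }
    }
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               file.path(rd, "metadata.json"))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rec_dir <- file.path(dir, "records")
  if (!dir.exists(rec_dir)) {
    stop("parse error: ", dir, " is not a dataset directory", call. = FALSE)
  }
  ids <- sort(list.dirs(rec_dir, recursive = FALSE, full.names = FALSE))
  records <- list()
  for (id in ids) {
    rd <- file.path(rec_dir, id)
    meta <- tryCatch(
      jsonlite::fromJSON(file.path(rd, "metadata.json"),
                         simplifyVector = TRUE),
      error = function(e) stop("parse error in ", rd, "/metadata.json: ",
                               conditionMessage(e), call. = FALSE))
    des <- meta$design
    design <- new_tablet_design(des$name, des$dr_frac, des$hpmc_frac,
                                des$mcc_frac, des$lactose_frac,
                                des$mgst_frac, des$size_fraction, des$role)
    rec <- list(design = design, replicate = meta$replicate,
                seed = meta$seed,
                profile = read_profile_csv(file.path(rd, "profile.csv")))
    for (m in names(meta$modalities)) {
      mm <- meta$modalities[[m]]
      fr <- read_matrix_csv(file.path(rd, paste0("fractions_", m, ".csv")),
                            mm$H * mm$W, 5)
      rec[[paste0("map_", m)]] <- structure(list(
        fractions = array(fr, c(mm$H, mm$W, 5),
                          dimnames = list(NULL, NULL, component_names())),
        pixel_pitch = mm$pixel_pitch, particles = NULL, design = design,
        seed = meta$seed), class = "particle_map")
      cube_path <- file.path(rd, paste0("cube_", m, ".csv"))
      if (file.exists(cube_path)) {
        cv <- read_matrix_csv(cube_path, mm$H * mm$W, mm$n_bands)
        rec[[paste0("cube_", m)]] <- structure(list(
          values = array(cv, c(mm$H, mm$W, mm$n_bands)),
          band_axis = seq_len(mm$n_bands), modality = m,
          pixel_pitch = mm$pixel_pitch), class = "hyper_cube")
      }
    }
    records[[id]] <- structure(rec, class = "ground_truth_record")
  }
  records
}

#' Write / read an experiment report as JSON
#'
#' Serialization is deterministic (fixed digit count, stable key order), so
#' identical configurations and master seeds yield byte-identical report
#' files.
#'
#' @param report an [run_experiment()] report.
#' @param path file path.
#' @return `read_report()` returns the report list; `write_report()` the
#'   path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rep <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("parse error in report ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  structure(rep, class = "experiment_report")
}

#' Export an ANN ensemble score table as CSV
#'
#' @param selection a [train_ensemble()] result.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_score_table <- function(selection, path) {
  stopifnot(inherits(selection, "selection_result"))
  write.csv(selection$scores, path, row.names = FALSE)
  invisible(path)
}
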