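#' Map geometries of the two imaging modalities
#'
#' Raman maps are 31 x 31 points at a 40 um step; NIR maps are 48 x 48 points
#' at a 25 um step; both cover about 1200 x 1200 um2 of the tablet face.
#'
#' @param modality `"raman"` or `"nir"`.
#' @return list with `grid_shape` (H, W) and `pixel_pitch` (um).
#' @export
map_geometry <- function(modality) {
  modality <- match.arg(modality, c("raman", "nir"))
  if (modality == "raman") {
    list(grid_shape = c(31L, 31L), pixel_pitch = 40)
  } else {
    list(grid_shape = c(48L, 48L), pixel_pitch = 25)
  }
}

#' Generate a per-pixel component-fraction map for one tablet face
#'
#' HPMC is placed as non-overlapping disk-shaped particles with diameters
#' drawn uniformly from the sieve-fraction interval, until the realized HPMC
#' area fraction is within `tolerance` of the design's w/w fraction (area
#' fraction is used as the w/w proxy, i.e. equal densities). The remaining
#' area of every pixel is filled with the homogeneous background mixture of
#' the other four components. Small particles give a homogeneous map; large
#' sieve fractions give high-intensity blobs separated by HPMC-free regions.
#'
#' @param design a [tablet_design()].
#' @param grid_shape integer `(H, W)`.
#' @param pixel_pitch pixel pitch in um.
#' @param seed integer seed.
#' @param tolerance acceptable |realized - target| area fraction
#'   (default 0.02).
#' @param max_attempts placement attempts before giving up (default 10,000).
#' @param supersample sub-samples per pixel edge used to rasterize disks.
#' @return a `particle_map`: `fractions` array H x W x 5 (component order
#'   `component_names()`), `pixel_pitch`, `particles` data frame
#'   (x, y, diameter in um), `design`.
#' @export
generate_particle_map <- function(design, grid_shape, pixel_pitch, seed = 1,
                                  tolerance = 0.02, max_attempts = 10000,
                                  supersample = 4) {
  stopifnot(inherits(design, "tablet_design"))
  H <- as.integer(grid_shape[1]); W <- as.integer(grid_shape[2])
  extent_y <- H * pixel_pitch
  extent_x <- W * pixel_pitch
  bounds <- sieve_bounds(design$size_fraction)
  if (min(extent_x, extent_y) < bounds[2]) {
    stop("grid extent smaller than the largest particle diameter",
         call. = FALSE)
  }
  set.seed(seed)
  target <- design$hpmc_frac
  area_total <- extent_x * extent_y

  px <- numeric(0); py <- numeric(0); pr <- numeric(0)
  frac <- 0
  attempts <- 0L
  while (target > 0 && frac < target - tolerance / 2) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(paste0(
        "particle placement failed: realized fraction %.4f of target %.4f ",
        "after %d attempts (%d particles placed)"),
        frac, target, max_attempts, length(pr)), call. = FALSE)
    }
    dd <- runif(1, bounds[1], bounds[2])
    r <- dd / 2
    if (2 * r >= min(extent_x, extent_y)) next
    x <- runif(1, r, extent_x - r)
    y <- runif(1, r, extent_y - r)
    if (length(pr) > 0 &&
        any((px - x)^2 + (py - y)^2 < (pr + r)^2)) next
    add <- pi * r^2 / area_total
    if (frac + add > target + tolerance / 2) next
    px <- c(px, x); py <- c(py, y); pr <- c(pr, r)
    frac <- frac + add
  }

  # Rasterize: per-pixel HPMC coverage via supersampling.
  hp <- matrix(0, H, W)
  if (length(pr) > 0) {
    ss <- supersample
    off <- (seq_len(ss) - 0.5) / ss
    for (k in seq_along(pr)) {
      r <- pr[k]
      i_lo <- max(1L, floor((py[k] - r) / pixel_pitch) + 1L)
      i_hi <- min(H, ceiling((py[k] + r) / pixel_pitch))
      j_lo <- max(1L, floor((px[k] - r) / pixel_pitch) + 1L)
      j_hi <- min(W, ceiling((px[k] + r) / pixel_pitch))
      for (i in i_lo:i_hi) {
        ys <- (i - 1 + off) * pixel_pitch
        dy2 <- (ys - py[k])^2
        for (j in j_lo:j_hi) {
          xs <- (j - 1 + off) * pixel_pitch
          cov <- sum(outer(dy2, (xs - px[k])^2, `+`) <= r^2) / ss^2
          if (cov > 0) hp[i, j] <- min(1, hp[i, j] + cov)
        }
      }
    }
  }

  bg <- design_fractions(design)[c("DR", "MCC", "lactose", "MgSt")]
  bg <- bg / sum(bg)
  fractions <- array(0, c(H, W, 5),
                     dimnames = list(NULL, NULL, component_names()))
  fractions[, , "HPMC"] <- hp
  for (nm in names(bg)) fractions[, , nm] <- (1 - hp) * bg[[nm]]

  structure(list(
    fractions = fractions, pixel_pitch = pixel_pitch,
    particles = data.frame(x = px, y = py, diameter = 2 * pr),
    realized_fraction = mean(hp), design = design, seed = seed
  ), class = "particle_map")
}

#' @export
print.particle_map <- function(x, ...) {
  d <- dim(x$fractions)
  cat(sprintf("<particle_map> %dx%d @ %g um, %d HPMC particles, area fraction %.3f (target %.3f)\n",
              d[1], d[2], x$pixel_pitch, nrow(x$particles),
              x$realized_fraction, x$design$hpmc_frac))
  invisible(x)
}

# Smooth positive 4th-order polynomial shape used as the fluorescence-like
# Raman baseline; t in [0, 1] along the band axis.
raman_baseline_shape <- function(n_bands) {
  t <- seq(0, 1, length.out = n_bands)
  0.6 + 2.0 * t - 1.6 * t^2 + 0.3 * t^3 + 0.2 * t^4
}

nir_baseline_shape <- function(n_bands) {
  t <- seq(0, 1, length.out = n_bands)
  0.2 + 0.3 * t
}

#' Render a hyperspectral cube from a particle map
#'
#' Linear mixing: each pixel spectrum is the fraction-weighted sum of the
#' pure component spectra, plus a smooth additive baseline and i.i.d.
#' Gaussian noise. For Raman-like libraries the baseline emulates MCC-driven
#' fluorescence (a 4th-order polynomial in band index scaled by the local MCC
#' fraction); for NIR-like libraries it is a gentle global slope.
#'
#' @param map a [generate_particle_map()] result.
#' @param library a [generate_pure_spectra()] result with matching
#'   components.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (intensity units; pure spectra have mean intensity 1).
#' @param baseline_amplitude scale of the additive baseline (0 disables it).
#' @param seed integer seed for the noise.
#' @param keep_baseline attach the per-pixel baseline matrix as attribute
#'   `baseline` (for testing; off by default to save memory).
#' @return a `hyper_cube`: `values` array H x W x B, `band_axis`, `modality`,
#'   `pixel_pitch`.
#' @export
render_cube <- function(map, library, noise_sd = 0, baseline_amplitude = 0,
                        seed = 1, keep_baseline = FALSE) {
  stopifnot(inherits(map, "particle_map"), inherits(library, "pure_library"))
  if (noise_sd < 0) stop("invalid-configuration: noise_sd must be >= 0",
                         call. = FALSE)
  comps <- component_names()
  if (!identical(dimnames(map$fractions)[[3]], comps) ||
      !identical(rownames(library$spectra), comps)) {
    stop("map and library components are inconsistent", call. = FALSE)
  }
  d <- dim(map$fractions)
  H <- d[1]; W <- d[2]
  B <- ncol(library$spectra)
  Fm <- matrix(map$fractions, H * W, 5)
  spec <- Fm %*% library$spectra

  base <- NULL
  if (baseline_amplitude > 0) {
    if (library$modality == "raman") {
      shape <- raman_baseline_shape(B)
      base <- baseline_amplitude * (Fm[, 3] %o% shape) # MCC-weighted
    } else {
      shape <- nir_baseline_shape(B)
      base <- baseline_amplitude * matrix(shape, H * W, B, byrow = TRUE)
    }
    spec <- spec + base
  }
  if (noise_sd > 0) {
    set.seed(seed)
    spec <- spec + matrix(rnorm(length(spec), 0, noise_sd), nrow(spec))
  }
  cube <- structure(list(values = array(spec, c(H, W, B)),
                         band_axis = library$band_axis,
                         modality = library$modality,
                         pixel_pitch = map$pixel_pitch),
                    class = "hyper_cube")
  if (keep_baseline && !is.null(base)) attr(cube, "baseline") <- base
  cube
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %s, %dx%d pixels x %d bands @ %g um\n",
              x$modality, d[1], d[2], d[3], x$pixel_pitch))
  invisible(x)
}

#' Simulate a ground-truth dissolution profile
#'
#' Weibull release `F(t) = 100 (1 - exp(-(t / tau)^beta))` with shape
#' `beta = 0.9` and time scale
#' `tau = 300 min * (c / 0.20)^1.2 * (45 / d_mid)^0.5`, where `c` is the
#' HPMC fraction and `d_mid` the sieve-interval midpoint in um. Release is
#' therefore slower (larger tau) at higher HPMC levels and faster for larger
#' HPMC particles, spanning the 16-hour window. Gaussian measurement noise is
#' added, then the profile is clipped to `[0, 100]` and made non-decreasing.
#'
#' @param design a [tablet_design()].
#' @param time_grid sampling times in minutes (default the 37-point
#'   schedule).
#' @param noise_sd measurement noise in release-% units.
#' @param seed integer seed.
#' @return a [dissolution_profile()].
#' @export
simulate_dissolution <- function(design, time_grid = dissolution_times(),
                                 noise_sd = 1, seed = 1) {
  stopifnot(inherits(design, "tablet_design"))
  tau <- dissolution_tau(design$hpmc_frac,
                         sieve_midpoint(design$size_fraction))
  f <- 100 * (1 - exp(-(time_grid / tau)^0.9))
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + rnorm(length(f), 0, noise_sd)
  }
  f <- pmin(pmax(f, 0), 100)
  dissolution_profile(time_grid, cummax(f))
}

# Weibull time scale of the ground-truth release model.
dissolution_tau <- function(hpmc_frac, d_mid_um) {
  300 * (hpmc_frac / 0.20)^1.2 * (45 / d_mid_um)^0.5
}

#' Generate a full synthetic dataset
#'
#' One ground-truth record per (design, replicate): a composition-jittered
#' design (multiplicative 1% noise on the HPMC fraction, emulating
#' tablet-to-tablet variation), Raman and NIR particle maps and cubes on the
#' standard geometries, and a measured-style dissolution profile. All seeds
#' derive from `master_seed` through a counter-based scheme, so the dataset
#' is a pure function of `(designs, replicates, master_seed)`.
#'
#' @param designs list of [tablet_design()] objects with unique names.
#' @param replicates tablets per design (>= 1).
#' @param master_seed integer master seed.
#' @param modalities character subset of `c("raman", "nir")`.
#' @param n_bands named bands per modality.
#' @param noise_sd named spectral noise per modality.
#' @param baseline_amplitude named baseline scale per modality.
#' @param similarity_target named HPMC-MCC correlation per modality.
#' @param profile_noise_sd dissolution measurement noise (%).
#' @param jitter_sd relative composition jitter.
#' @param include_cubes render and keep the hyperspectral cubes (set `FALSE`
#'   to generate only designs, maps and profiles, e.g. for large structural
#'   checks).
#' @return list of `ground_truth_record` objects, plus attribute `libraries`
#'   (the shared pure libraries per modality).
#' @export
generate_dataset <- function(designs, replicates = 4, master_seed = 1,
                             modalities = c("raman", "nir"),
                             n_bands = c(raman = 300, nir = 220),
                             noise_sd = c(raman = 0.02, nir = 0.02),
                             baseline_amplitude = c(raman = 2, nir = 0.2),
                             similarity_target = c(raman = 0.6, nir = 0.92),
                             profile_noise_sd = 1, jitter_sd = 0.01,
                             include_cubes = TRUE) {
  stopifnot(replicates >= 1)
  modalities <- match.arg(modalities, c("raman", "nir"), several.ok = TRUE)
  nms <- vapply(designs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("invalid-configuration: duplicate design names", call. = FALSE)
  }
  libs <- lapply(seq_along(modalities), function(i) {
    m <- modalities[i]
    generate_pure_spectra(m, n_bands[[m]], similarity_target[[m]],
                          seed = derive_seed(master_seed, i))
  })
  names(libs) <- modalities

  records <- list()
  idx <- 0L
  for (d in designs) {
    for (rep_i in seq_len(replicates)) {
      idx <- idx + 1L
      rec_seed <- derive_seed(master_seed, 100 + idx)
      jd <- jitter_design(d, jitter_sd, seed = derive_seed(rec_seed, 1))
      rec <- list(design = jd, nominal_design = d, replicate = rep_i,
                  seed = rec_seed,
                  profile = simulate_dissolution(
                    jd, noise_sd = profile_noise_sd,
                    seed = derive_seed(rec_seed, 2)))
      for (m in modalities) {
        geom <- map_geometry(m)
        pm <- generate_particle_map(jd, geom$grid_shape, geom$pixel_pitch,
                                    seed = derive_seed(rec_seed,
                                                       match(m, modalities) + 2))
        rec[[paste0("map_", m)]] <- pm
        if (include_cubes) {
          rec[[paste0("cube_", m)]] <- render_cube(
            pm, libs[[m]], noise_sd = noise_sd[[m]],
            baseline_amplitude = baseline_amplitude[[m]],
            seed = derive_seed(rec_seed, match(m, modalities) + 10))
        }
      }
      records[[idx]] <- structure(rec, class = "ground_truth_record")
    }
  }
  names(records) <- vapply(records, function(r)
    sprintf("%s_r%d", r$design$name, r$replicate), character(1))
  attr(records, "libraries") <- libs
  records
}
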