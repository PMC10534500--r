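# Synthetic-data generator: pure spectra, particle maps, cube rendering,
# dissolution model, dataset assembly.

test_that("pure spectra are deterministic and hit the similarity target", {
  a <- generate_pure_spectra("raman", 400, 0.9, seed = 1)
  b <- generate_pure_spectra("raman", 400, 0.9, seed = 1)
  expect_identical(a$spectra, b$spectra)
  r <- cor(a$spectra["HPMC", ], a$spectra["MCC", ])
  expect_gte(r, 0.85)
  expect_lte(r, 0.95)
  for (tgt in c(0.3, 0.6, 0.95)) {
    lib <- generate_pure_spectra("nir", 220, tgt, seed = 2)
    expect_equal(cor(lib$spectra["HPMC", ], lib$spectra["MCC", ]), tgt,
                 tolerance = 0.05 / tgt)
  }
})

test_that("Raman components carry several distinct peaks, NIR peaks are broader", {
  for (seed in 1:3) {
    lib <- generate_pure_spectra("raman", 400, 0.6, seed = seed)
    n_pk <- apply(lib$spectra, 1, dissmap:::count_peaks)
    expect_true(all(n_pk >= 3))
    nir <- generate_pure_spectra("nir", 400, 0.9, seed = seed)
    expect_gt(median(unlist(lapply(nir$peaks, `[[`, "width"))),
              median(unlist(lapply(lib$peaks, `[[`, "width"))))
  }
})

test_that("pure spectra generation rejects invalid configurations", {
  expect_error(generate_pure_spectra("raman", 30), "n_bands")
  expect_error(generate_pure_spectra("raman", 400, similarity_target = 1),
               "similarity_target")
})

test_that("particle maps realize the target HPMC fraction with valid pixels", {
  d <- tablet_design("pm1", 0.20, "<45")
  pm <- generate_particle_map(d, c(48, 48), 25, seed = 2, tolerance = 0.02)
  expect_gte(pm$realized_fraction, 0.18)
  expect_lte(pm$realized_fraction, 0.22)
  sums <- apply(pm$fractions, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(pm$fractions >= 0))
})

test_that("placed particle diameters respect the sieve bounds", {
  for (fr in hpmc_size_levels()) {
    d <- tablet_design("pm2", 0.15, fr)
    pm <- generate_particle_map(d, c(31, 31), 40, seed = 3)
    bounds <- sieve_bounds(fr)
    expect_true(all(pm$particles$diameter >= bounds[1]))
    expect_true(all(pm$particles$diameter < bounds[2]))
    # non-overlap
    if (nrow(pm$particles) > 1) {
      dd <- as.matrix(dist(pm$particles[, c("x", "y")]))
      rr <- outer(pm$particles$diameter / 2, pm$particles$diameter / 2, `+`)
      diag(dd) <- Inf
      expect_true(all(dd >= rr - 1e-9))
    }
  }
})

test_that("a zero-HPMC map is pure background", {
  d0 <- structure(list(name = "bg", dr_frac = 0.08, hpmc_frac = 0,
                       mcc_frac = 0.2, lactose_frac = 0.7, mgst_frac = 0.02,
                       size_fraction = "<45", role = "calibration"),
                  class = "tablet_design")
  pm <- generate_particle_map(d0, c(16, 16), 40, seed = 1)
  expect_equal(nrow(pm$particles), 0)
  expect_true(all(pm$fractions[, , "HPMC"] == 0))
  expect_equal(pm$fractions[3, 3, "lactose"], 0.7, ignore_attr = TRUE)
})

test_that("rendering is the exact linear mixing model when clean", {
  lib <- generate_pure_spectra("nir", 120, 0.8, seed = 5)
  d <- tablet_design("rc", 0.3, "45-63")
  # one pure-HPMC pixel, one 0.3/0.7 HPMC/background pixel
  hp <- matrix(c(1, 0.3, 0, 0.6), 2, 2)
  pm <- manual_particle_map(hp, d)
  cube <- render_cube(pm, lib, noise_sd = 0, baseline_amplitude = 0)
  expect_equal(as.numeric(cube$values[1, 1, ]),
               as.numeric(lib$spectra["HPMC", ]), tolerance = 1e-12)
  # matrix-product oracle for the mixed pixel
  fr <- pm$fractions[2, 1, ]
  oracle <- as.numeric(fr %*% lib$spectra)
  expect_equal(as.numeric(cube$values[2, 1, ]), oracle, tolerance = 1e-12)
})

test_that("the rendered baseline separates additively from the mixture", {
  lib <- generate_pure_spectra("raman", 150, 0.6, seed = 6)
  d <- tablet_design("rb", 0.2, "63-100")
  pm <- generate_particle_map(d, c(10, 10), 40, seed = 7)
  clean <- render_cube(pm, lib, noise_sd = 0, baseline_amplitude = 0)
  dirty <- render_cube(pm, lib, noise_sd = 0, baseline_amplitude = 2,
                       keep_baseline = TRUE)
  base <- attr(dirty, "baseline")
  expect_false(is.null(base))
  diff <- matrix(dirty$values, 100, 150) - base
  expect_equal(diff, matrix(clean$values, 100, 150), tolerance = 1e-12)
  expect_error(render_cube(pm, lib, noise_sd = -1), "noise_sd")
})

test_that("dissolution is slower with more HPMC and faster with larger particles", {
  tg <- dissolution_times()
  i480 <- which(tg == 480)
  lo <- simulate_dissolution(tablet_design("a", 0.10, "<45"), noise_sd = 0)
  hi <- simulate_dissolution(tablet_design("b", 0.30, "<45"), noise_sd = 0)
  expect_lt(hi$released[i480], lo$released[i480])
  fine <- simulate_dissolution(tablet_design("c", 0.25, "<45"), noise_sd = 0)
  coarse <- simulate_dissolution(tablet_design("d", 0.25, "100-150"),
                                 noise_sd = 0)
  expect_gt(coarse$released[i480], fine$released[i480])
  # pointwise monotonicity in HPMC at fixed size (beyond t = 0 trivial ties)
  concs <- c(0.10, 0.15, 0.20, 0.25, 0.30)
  rel <- sapply(concs, function(cc)
    simulate_dissolution(tablet_design("m", cc, "45-63"),
                         noise_sd = 0)$released)
  expect_true(all(apply(rel, 1, function(r) all(diff(r) <= 1e-12))))
})

test_that("noise-free profiles are valid release curves", {
  for (fr in hpmc_size_levels()) {
    p <- simulate_dissolution(tablet_design("v", 0.17, fr), noise_sd = 0)
    expect_length(p$released, 37)
    expect_true(all(p$released >= 0 & p$released <= 100))
    expect_true(all(diff(p$released) >= 0))
  }
  # noisy profiles are clipped and monotone too
  p <- simulate_dissolution(tablet_design("v", 0.12, "<45"), noise_sd = 3,
                            seed = 8)
  expect_true(all(p$released >= 0 & p$released <= 100))
  expect_true(all(diff(p$released) >= 0))
})

test_that("dataset assembly yields one record per design x replicate", {
  designs <- experiment_designs()
  cal <- Filter(function(d) d$role == "calibration", designs)
  val <- Filter(function(d) d$role == "validation", designs)
  ds_cal <- generate_dataset(cal, replicates = 4, master_seed = 1,
                             include_cubes = FALSE)
  expect_length(ds_cal, 112)
  ds_val <- generate_dataset(val, replicates = 4, master_seed = 1,
                             include_cubes = FALSE)
  expect_length(ds_val, 32)
  # duplicate names rejected
  expect_error(generate_dataset(c(cal[1], cal[1]), 1, 1,
                                include_cubes = FALSE), "duplicate")
})

test_that("dataset generation is a pure function of its seeds", {
  designs <- experiment_designs()[c(1, 9, 30)]
  a <- generate_dataset(designs, replicates = 2, master_seed = 42,
                        n_bands = c(raman = 80, nir = 70))
  b <- generate_dataset(designs, replicates = 2, master_seed = 42,
                        n_bands = c(raman = 80, nir = 70))
  expect_identical(a[["DR01_r2"]]$cube_raman$values,
                   b[["DR01_r2"]]$cube_raman$values)
  expect_identical(a[["DR09_r1"]]$profile$released,
                   b[["DR09_r1"]]$profile$released)
  expect_identical(a[["DRV02_r1"]]$map_nir$fractions,
                   b[["DRV02_r1"]]$map_nir$fractions)
  # different master seed changes the data
  c1 <- generate_dataset(designs[1], replicates = 1, master_seed = 43,
                         n_bands = c(raman = 80, nir = 70))
  expect_false(identical(a[["DR01_r1"]]$cube_raman$values,
                         c1[["DR01_r1"]]$cube_raman$values))
})

test_that("the experimental design table matches its stated structure", {
  df <- experiment_designs(as_data_frame = TRUE)
  expect_equal(nrow(df), 36)
  expect_equal(sum(df$role == "calibration"), 28)
  expect_equal(sum(df$role == "validation"), 8)
  expect_setequal(unique(df$size_fraction), hpmc_size_levels())
  cal <- df[df$role == "calibration", ]
  expect_equal(sort(unique(cal$hpmc_pct)),
               c(10, 13.33, 16.66, 20, 23.33, 26.66, 30))
  # every design sums to 100% and validation concentrations interleave
  designs <- experiment_designs()
  sums <- vapply(designs, function(d)
    d$dr_frac + d$hpmc_frac + d$mcc_frac + d$lactose_frac + d$mgst_frac,
    numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(tablet_design("bad", 0.05, "<45"), "hpmc_frac")
  expect_error(tablet_design("bad", 0.35, "<45"), "hpmc_frac")
})
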