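# Classical least squares unmixing and concentration-map features.

test_that("the operator is the pseudo-inverse: identity on the library", {
  lib <- generate_pure_spectra("nir", 150, 0.8, seed = 1)
  lib_pp <- preprocess_nir(lib)
  op <- fit_cls(lib_pp)
  expect_lt(max(abs(op$matrix %*% t(lib_pp$spectra) - diag(5))), 1e-8)
  expect_gt(op$condition_number, 1)
})

test_that("an orthonormal library is its own unmixing operator", {
  q <- qr.Q(qr(matrix(rnorm(60 * 3), 60, 3)))
  S <- t(q) # 3 orthonormal rows
  rownames(S) <- c("A", "B", "C")
  op <- fit_cls(S)
  expect_equal(op$matrix, S, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a duplicated component makes unmixing infeasible", {
  lib <- generate_pure_spectra("raman", 120, 0.5, seed = 2)
  S <- lib$spectra
  S["MCC", ] <- S["HPMC", ]
  expect_error(fit_cls(S), "rank deficient")
})

test_that("pixel unmixing recovers pure and mixed spectra, clamping negatives", {
  lib <- generate_pure_spectra("nir", 130, 0.7, seed = 3)
  lib_pp <- preprocess_nir(lib)
  op <- fit_cls(lib_pp)
  a <- unmix_pixel(op, lib_pp$spectra["HPMC", ])
  expect_equal(unname(a["HPMC"]), 1, tolerance = 1e-9)
  expect_equal(unname(a[c("DR", "MCC", "lactose", "MgSt")]), rep(0, 4),
               tolerance = 1e-9)
  # general least-squares oracle on a 0.3/0.7 mixture
  mix <- 0.3 * lib_pp$spectra["HPMC", ] + 0.7 * lib_pp$spectra["MCC", ]
  oracle <- coef(lm(mix ~ t(lib_pp$spectra) - 1))
  expect_equal(unname(unmix_pixel(op, mix)), unname(pmax(oracle, 0)),
               tolerance = 1e-9)
  expect_equal(unname(unmix_pixel(op, mix)[c("HPMC", "MCC")]), c(0.3, 0.7),
               tolerance = 1e-9)
  # negative spectrum clamps to zero
  expect_equal(unname(unmix_pixel(op, -lib_pp$spectra["HPMC", ])["HPMC"]), 0)
  expect_error(unmix_pixel(op, 1:10), "length")
})

test_that("noiseless NIR cubes unmix to the generator ground truth", {
  lib <- generate_pure_spectra("nir", 220, 0.92, seed = 4)
  d <- tablet_design("cls1", 0.2, "63-100")
  pm <- generate_particle_map(d, c(48, 48), 25, seed = 5)
  cube <- render_cube(pm, lib, noise_sd = 0, baseline_amplitude = 0)
  op <- fit_cls(preprocess_nir(lib))
  cm <- concentration_map(op, preprocess_nir(cube), "HPMC")
  expect_equal(dim(cm$values), c(48, 48))
  expect_lt(max(abs(cm$values - 100 * pm$fractions[, , "HPMC"])), 1e-6)
})

test_that("map geometries give 31x31 Raman and 48x48 NIR maps", {
  for (m in c("raman", "nir")) {
    geom <- map_geometry(m)
    lib <- generate_pure_spectra(m, 100, 0.5, seed = 6)
    d <- tablet_design("geo", 0.15, "45-63")
    pm <- generate_particle_map(d, geom$grid_shape, geom$pixel_pitch,
                                seed = 7)
    cube <- render_cube(pm, lib, noise_sd = 0, baseline_amplitude = 0)
    cm <- concentration_map(fit_cls(preprocess_modality(lib, m)),
                            preprocess_modality(cube, m), "HPMC")
    expect_equal(dim(cm$values), geom$grid_shape)
  }
  expect_equal(map_geometry("raman")$grid_shape, c(31L, 31L))
  expect_equal(map_geometry("raman")$pixel_pitch, 40)
  expect_equal(map_geometry("nir")$grid_shape, c(48L, 48L))
  expect_equal(map_geometry("nir")$pixel_pitch, 25)
})

test_that("a cube without HPMC unmixes to a near-zero HPMC map", {
  lib <- generate_pure_spectra("nir", 120, 0.8, seed = 8)
  d <- tablet_design("bg", 0.1, "<45")
  hp <- matrix(0, 6, 6)
  pm <- manual_particle_map(hp, d)
  cube <- render_cube(pm, lib, noise_sd = 0, baseline_amplitude = 0)
  cm <- concentration_map(fit_cls(preprocess_nir(lib)),
                          preprocess_nir(cube), "HPMC")
  expect_lt(max(abs(cm$values)), 1e-6)
})

test_that("mean concentration is the plain pixel average", {
  cm <- structure(list(values = matrix(20, 5, 5), component = "HPMC",
                       pixel_pitch = 40), class = "conc_map")
  expect_equal(mean_concentration(cm), 20)
  cm$values <- matrix(c(rep(0, 12), rep(40, 12), 20), 5, 5)
  expect_equal(mean_concentration(cm), 20)
  set.seed(9)
  cm$values <- matrix(runif(25, 0, 40), 5, 5)
  acc <- 0
  for (v in as.numeric(cm$values)) acc <- acc + v
  expect_equal(mean_concentration(cm), acc / 25, tolerance = 1e-12)
})

test_that("pixel noise raises recovery error monotonically", {
  lib <- generate_pure_spectra("nir", 120, 0.8, seed = 10)
  d <- tablet_design("nz", 0.2, "45-63")
  pm <- generate_particle_map(d, c(16, 16), 40, seed = 11)
  op <- fit_cls(preprocess_nir(lib))
  rmse_at <- function(noise) {
    errs <- vapply(1:4, function(s) {
      cube <- render_cube(pm, lib, noise_sd = noise,
                          baseline_amplitude = 0, seed = 100 + s)
      cm <- concentration_map(op, preprocess_nir(cube), "HPMC")
      sqrt(mean((cm$values - 100 * pm$fractions[, , "HPMC"])^2))
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(0.005, 0.02, 0.08), rmse_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("higher HPMC-MCC similarity inflates recovery error", {
  d <- tablet_design("sim", 0.2, "45-63")
  pm <- generate_particle_map(d, c(16, 16), 40, seed = 12)
  err_at <- function(target) {
    errs <- vapply(1:4, function(s) {
      lib <- generate_pure_spectra("nir", 120, target, seed = 200 + s)
      cube <- render_cube(pm, lib, noise_sd = 0.02,
                          baseline_amplitude = 0, seed = 300 + s)
      cm <- concentration_map(fit_cls(preprocess_nir(lib)),
                              preprocess_nir(cube), "HPMC")
      sqrt(mean((cm$values - 100 * pm$fractions[, , "HPMC"])^2))
    }, numeric(1))
    mean(errs)
  }
  expect_gt(err_at(0.97), err_at(0.3))
})

test_that("Raman recipe recovery is proportional with unit slope", {
  lib <- generate_pure_spectra("raman", 300, 0.6, seed = 13)
  d <- tablet_design("rr", 0.2, "63-100")
  pm <- generate_particle_map(d, c(31, 31), 40, seed = 14)
  cube <- render_cube(pm, lib, noise_sd = 0, baseline_amplitude = 2,
                      seed = 15)
  op <- fit_cls(preprocess_raman(lib))
  cm <- concentration_map(op, preprocess_raman(cube), "HPMC")
  truth <- 100 * pm$fractions[, , "HPMC"]
  fit <- lm(as.numeric(cm$values) ~ as.numeric(truth))
  expect_gt(summary(fit)$r.squared, 0.98)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
})
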