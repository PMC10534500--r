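# Particle-size CNN: architecture arithmetic, exact gradients, learning-rate
# schedule, split logic and training behavior.

test_that("parameter counts are a deterministic function of the architecture", {
  m1 <- build_particle_cnn(c(31, 31), seed = 1)
  m2 <- build_particle_cnn(c(31, 31), seed = 99)
  expect_identical(cnn_param_count(m1), cnn_param_count(m2))
  # independent arithmetic for the default config at 31x31 (pool 4):
  # conv1 9*16+16, bn1 32, conv2 9*16*16+16, bn2 32, flat 1*1*16,
  # fc 16*32+32, out 32+1
  expect_identical(cnn_param_count(m1),
                   as.integer((9 * 16 + 16) + 32 + (9 * 16 * 16 + 16) + 32 +
                                (16 * 32 + 32) + 33))
  # both stated map geometries are accepted
  expect_s3_class(build_particle_cnn(c(31, 31)), "particle_cnn")
  expect_s3_class(build_particle_cnn(c(48, 48)), "particle_cnn")
})

test_that("over-pooling the input is an invalid architecture", {
  expect_error(build_particle_cnn(c(8, 8), filters = c(8, 8, 8), pool = 4),
               "invalid-architecture")
  expect_error(build_particle_cnn(c(4, 4)), "at least 8")
})

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  m <- build_particle_cnn(c(12, 12), filters = c(3, 3), fc_units = 4,
                          dropout_rate = 0, pool = 2, seed = 7)
  X <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  y <- rnorm(3)
  lg <- dissmap:::cnn_loss_and_grads(m, X, y, train = TRUE)
  num_grad <- function(get, set, ana) {
    eps <- 1e-5
    p0 <- get(m)
    for (i in seq_along(p0)) {
      mp <- set(m, replace(p0, i, p0[i] + eps))
      mm <- set(m, replace(p0, i, p0[i] - eps))
      ng <- (dissmap:::cnn_loss_and_grads(mp, X, y, train = TRUE)$loss -
               dissmap:::cnn_loss_and_grads(mm, X, y, train = TRUE)$loss) /
        (2 * eps)
      expect_equal(ana[i], ng, tolerance = 1e-5)
    }
  }
  num_grad(function(m) as.numeric(m$params$conv[[1]]$W[1:5, 1]),
           function(m, v) { m$params$conv[[1]]$W[1:5, 1] <- v; m },
           as.numeric(lg$grads$conv[[1]]$W[1:5, 1]))
  num_grad(function(m) m$params$conv[[2]]$b,
           function(m, v) { m$params$conv[[2]]$b <- v; m },
           lg$grads$conv[[2]]$b)
  num_grad(function(m) m$params$bn[[1]]$gamma,
           function(m, v) { m$params$bn[[1]]$gamma <- v; m },
           lg$grads$bn[[1]]$gamma)
  num_grad(function(m) m$params$bn[[2]]$beta,
           function(m, v) { m$params$bn[[2]]$beta <- v; m },
           lg$grads$bn[[2]]$beta)
  num_grad(function(m) as.numeric(m$params$fc$W[1:4, 1]),
           function(m, v) { m$params$fc$W[1:4, 1] <- v; m },
           as.numeric(lg$grads$fc$W[1:4, 1]))
  num_grad(function(m) as.numeric(m$params$out$W),
           function(m, v) { m$params$out$W[] <- v; m },
           as.numeric(lg$grads$out$W))
})

test_that("the staircase learning-rate schedule matches its closed form", {
  expect_equal(lr_schedule(11), 0.0009)
  expect_equal(lr_schedule(21), 0.00081)
  for (e in 1:100) {
    expect_equal(lr_schedule(e), 0.001 * 0.9^floor((e - 1) / 10))
  }
  expect_equal(lr_schedule(1), 0.001)
  expect_equal(lr_schedule(10), 0.001)
})

test_that("train/val splits are disjoint, exhaustive, stratified, deterministic", {
  strata <- expand.grid(conc = 1:7, size = hpmc_size_levels(),
                        rep = 1:4)[, 1:2]
  sp <- split_train_val(strata, 16, seed = 3)
  expect_length(sp$val, 16)
  expect_length(sp$train, 96)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), seq_len(112))
  # one pick per stratum when n_val is a multiple of the stratum count is
  # impossible here (28 strata, 16 picks) but no stratum may donate twice
  # before every stratum has donated once
  lab <- interaction(strata)
  expect_true(all(table(lab[sp$val]) <= 1))
  sp2 <- split_train_val(strata, 16, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_val(strata, 16, seed = 4)))
  expect_error(split_train_val(strata, 112, seed = 1),
               "invalid-configuration")
})

test_that("training with zero dropout and a fixed seed is bit-reproducible", {
  set.seed(20)
  maps <- lapply(1:16, function(i) matrix(runif(16 * 16), 16, 16))
  labels <- rep(c(45, 63, 100, 150), 4)
  run <- function() {
    m <- build_particle_cnn(c(16, 16), filters = c(4, 4), fc_units = 8,
                            dropout_rate = 0, pool = 2, seed = 5)
    train_particle_cnn(m, maps, labels,
                       cfg = cnn_train_config(max_epochs = 4, seed = 9))
  }
  a <- run()
  b <- run()
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("training reduces the loss on a clean high-contrast set", {
  set.seed(21)
  # maps whose texture scale encodes the label
  mk <- function(size) {
    m <- matrix(0, 16, 16)
    step <- max(1, round(size / 30))
    m[seq(1, 16, by = step + 1), ] <- 100
    m + matrix(rnorm(256, 0, 1), 16, 16)
  }
  labels <- rep(c(45, 63, 100, 150), 6)
  maps <- lapply(labels, mk)
  m <- build_particle_cnn(c(16, 16), filters = c(8, 8), fc_units = 16,
                          pool = 2, seed = 2)
  m <- train_particle_cnn(m, maps, labels,
                          cfg = cnn_train_config(max_epochs = 30, seed = 3))
  h <- m$history
  expect_lt(mean(tail(h$train_loss, 3)), h$train_loss[1])
  pred <- predict_size(m, maps)
  expect_true(all(is.finite(pred)))
  expect_true(all(pred >= 22.5 & pred <= 200))
})

test_that("a sparsely trained size class is predicted low", {
  # When the largest fraction is nearly absent from training, its tablets
  # are systematically under-predicted relative to a fully trained model —
  # the shrinkage behavior expected of a regression CNN on unbalanced data.
  master <- 101
  bench <- make_size_benchmark(master, c(31, 31), 40)
  lab_cal <- bench$labels[bench$cal]
  run_with <- function(n150) {
    keep <- rep(TRUE, length(bench$cal))
    idx150 <- which(lab_cal == 150)
    keep[idx150[-seq_len(n150)]] <- FALSE
    tr <- bench$cal[keep]
    cnn <- build_particle_cnn(c(31, 31), seed = derive_seed(master, 900))
    cnn <- train_particle_cnn(
      cnn, bench$maps[tr], bench$labels[tr],
      cfg = cnn_train_config(seed = derive_seed(master, 901),
                             max_epochs = 60))
    pred <- predict_size(cnn, bench$maps[bench$val])
    mean(pred[bench$labels[bench$val] == 150])
  }
  full <- run_with(sum(lab_cal == 150))
  sparse <- run_with(2)
  expect_lt(sparse, full - 5)
  expect_lt(sparse, 140)
})

test_that("prediction validates fit state and input shape", {
  m <- build_particle_cnn(c(16, 16), filters = c(4, 4), pool = 2, seed = 1)
  expect_error(predict_size(m, matrix(0, 16, 16)), "not-fitted")
  maps <- lapply(1:8, function(i) matrix(runif(256), 16, 16))
  m <- train_particle_cnn(m, maps, rep(c(45, 150), 4),
                          cfg = cnn_train_config(max_epochs = 2, seed = 1))
  expect_error(predict_size(m, matrix(0, 31, 31)), "shape")
})

test_that("cnn training config validates and records defaults", {
  cfg <- cnn_train_config()
  expect_equal(cfg$initial_lr, 0.001)
  expect_equal(cfg$lr_drop_period, 10)
  expect_equal(cfg$lr_drop_factor, 0.9)
  expect_equal(cfg$max_epochs, 100L)
  expect_equal(cfg$validation_every, 5L)
  expect_error(cnn_train_config(max_epochs = 0), "")
})
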