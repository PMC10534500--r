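# Dissolution ANN: topology, Bayesian-regularized LM training, ensemble
# selection.

test_that("parameter counts follow the 40h + 37 formula", {
  expect_equal(ann_param_count(3), 157L)
  for (h in 1:10) {
    expect_equal(ann_param_count(h),
                 as.integer(2 * h + h + 37 * h + 37))
  }
})

test_that("hidden width is restricted to 1-10 and activations are bounded", {
  expect_error(build_ann(0), "1-10")
  expect_error(build_ann(11), "1-10")
  m <- build_ann(4, seed = 2)
  set.seed(3)
  X <- matrix(rnorm(40, 0, 2), 20, 2)
  A <- dissmap:::ann_forward_std(m, X)$A
  expect_true(all(A > -1 & A < 1))
  # extreme inputs saturate but never exceed the bounds
  Aext <- dissmap:::ann_forward_std(m, matrix(c(-1e6, 1e6, 0, 0), 2, 2))$A
  expect_true(all(Aext >= -1 & Aext <= 1))
})

test_that("structured gradient and Gauss-Newton equal the explicit Jacobian", {
  for (h in c(1, 4, 9)) {
    m <- build_ann(h, seed = h + 10)
    set.seed(h)
    N <- 11
    Xz <- matrix(rnorm(2 * N), N, 2)
    Yz <- matrix(rnorm(37 * N), N, 37)
    fw <- dissmap:::ann_forward_std(m, Xz)
    E <- fw$Y - Yz
    J <- dissmap:::ann_jacobian(m, Xz, fw$A)
    expect_equal(dissmap:::ann_grad_ed(m, Xz, fw$A, E),
                 as.numeric(crossprod(J, as.numeric(t(E)))),
                 tolerance = 1e-10)
    expect_equal(dissmap:::ann_gauss_newton(m, Xz, fw$A), crossprod(J),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("training fits noiseless linear data to near machine precision", {
  set.seed(31)
  N <- 60
  X <- cbind(runif(N, 10, 30), runif(N, 45, 150))
  A <- matrix(runif(37 * 2, -0.5, 0.5), 37, 2)
  Y <- X %*% t(A) + matrix(rnorm(37, 50, 5), N, 37, byrow = TRUE)
  m <- train_bayesreg(build_ann(3, seed = 1), X, Y, max_epochs = 300)
  Xz <- sweep(sweep(X, 2, m$input_scaler$mean), 2, m$input_scaler$sd, `/`)
  Yz <- sweep(sweep(Y, 2, m$output_scaler$mean), 2, m$output_scaler$sd, `/`)
  pred <- dissmap:::ann_forward_std(m, Xz)$Y
  expect_lt(mean((pred - Yz)^2), 1e-3)
  expect_lte(m$epochs_used, 300)
  expect_true(m$termination %in% c("max_epochs", "min_grad", "mu_max"))
  expect_gt(m$final_alpha, 0)
  expect_gt(m$final_beta, 0)
  expect_gte(m$final_gamma, 0)
  expect_lte(m$final_gamma, ann_param_count(3))
})

test_that("the gradient stopping rule fires on its infinity norm", {
  set.seed(32)
  X <- cbind(runif(20, 10, 30), runif(20, 45, 150))
  Y <- matrix(runif(20 * 37, 0, 100), 20, 37)
  m <- train_bayesreg(build_ann(2, seed = 1), X, Y, grad_tol = 1e6)
  expect_equal(m$termination, "min_grad")
  expect_equal(m$epochs_used, 0L)
})

test_that("with regularization off, one step is a plain LM step on the MSE", {
  set.seed(33)
  N <- 15
  X <- cbind(runif(N, 10, 30), runif(N, 45, 150))
  Y <- matrix(runif(N * 37, 0, 100), N, 37)
  m0 <- build_ann(2, seed = 7)
  trained <- train_bayesreg(m0, X, Y, max_epochs = 1,
                            regularization = "none")
  # oracle: standardize, one LM trial with alpha = 0, beta = 1, mu = 0.005
  xm <- colMeans(X); xs <- apply(X, 2, sd)
  ym <- colMeans(Y); ys <- apply(Y, 2, sd)
  Xz <- sweep(sweep(X, 2, xm), 2, xs, `/`)
  Yz <- sweep(sweep(Y, 2, ym), 2, ys, `/`)
  w <- dissmap:::ann_pack(m0)
  fw <- dissmap:::ann_forward_std(m0, Xz)
  J <- dissmap:::ann_jacobian(m0, Xz, fw$A)
  e <- as.numeric(t(fw$Y - Yz))
  mu <- 0.005
  F0 <- 0.5 * sum(e^2)
  repeat {
    H <- crossprod(J)
    diag(H) <- diag(H) + mu
    w_try <- w + as.numeric(solve(H, -crossprod(J, e)))
    m_try <- dissmap:::ann_unpack(m0, w_try)
    e_try <- as.numeric(t(dissmap:::ann_forward_std(m_try, Xz)$Y - Yz))
    if (0.5 * sum(e_try^2) < F0) break
    mu <- mu * 10
  }
  expect_equal(dissmap:::ann_pack(trained), w_try, tolerance = 1e-8)
  # unregularized objective equals the data misfit alone
  expect_equal(trained$history$objective, trained$history$Ed)
})

test_that("ensemble training scores every (width, run) pair and picks the max", {
  set.seed(34)
  N <- 24
  X <- cbind(runif(N, 10, 30), sample(c(45, 150), N, TRUE))
  Y <- t(sapply(seq_len(N), function(i)
    100 * (1 - exp(-(dissolution_times() / (10 * X[i, 1]))^0.9))))
  Xv <- X[1:4, ]
  vp <- lapply(1:4, function(i) dissolution_profile(released = Y[i, ]))
  sel <- train_ensemble(X, Y, Xv, vp, runs = 2, hidden_range = 1:2,
                        master_seed = 5, max_epochs = 15)
  expect_equal(nrow(sel$scores), 4)
  expect_equal(sel$best_score, max(sel$scores$mean_f2))
  expect_equal(
    sel$scores$mean_f2[sel$scores$n_hidden == sel$best_n_hidden &
                         sel$scores$run == sel$best_run],
    sel$best_score)
  # determinism
  sel2 <- train_ensemble(X, Y, Xv, vp, runs = 2, hidden_range = 1:2,
                         master_seed = 5, max_epochs = 15)
  expect_identical(sel$scores, sel2$scores)
  expect_identical(sel$best_model$W1, sel2$best_model$W1)
})

test_that("a trained model predicts slower release for more HPMC", {
  dat <- make_gt_ann_data(replicates = 1)
  m <- train_bayesreg(build_ann(4, seed = 2), dat$Xtr, dat$Ytr,
                      max_epochs = 100)
  i480 <- which(dissolution_times() == 480)
  lo <- predict_profile(m, 12, 63)$released[i480]
  hi <- predict_profile(m, 28, 63)$released[i480]
  expect_lt(hi, lo)
})

test_that("profile prediction emits 37 clamped points on the fixed grid", {
  set.seed(35)
  N <- 30
  X <- cbind(runif(N, 10, 30), sample(c(45, 63, 100, 150), N, TRUE))
  Y <- t(sapply(seq_len(N), function(i)
    simulate_dissolution(tablet_design("t", X[i, 1] / 100, "<45"),
                         noise_sd = 0)$released))
  expect_error(predict_profile(build_ann(2, seed = 1), 20, 100),
               "not-fitted")
  m <- train_bayesreg(build_ann(3, seed = 1), X, Y, max_epochs = 40)
  p <- predict_profile(m, 20, 100)
  expect_s3_class(p, "dissolution_profile")
  expect_length(p$released, 37)
  expect_equal(p$times, dissolution_times())
  expect_true(all(p$released >= 0 & p$released <= 110))
})
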