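# Single-hidden-layer feedforward network (2 inputs -> 1..10 tansig hidden
# units -> 37 linear outputs) mapping (mean HPMC concentration, HPMC particle
# size) to a dissolution profile. Trained by Levenberg-Marquardt on the
# Bayesian-regularized objective beta * Ed + alpha * Ew with MacKay evidence
# updates of (alpha, beta, gamma) each epoch — the classical "trainbr"
# recipe.

#' Parameter count of the dissolution ANN
#'
#' `(2 + 1) * n_hidden` input-side weights and biases plus
#' `(n_hidden + 1) * 37` output-side, i.e. `40 * n_hidden + 37`.
#'
#' @param n_hidden hidden-layer width.
#' @param n_outputs output width (default 37).
#' @return integer parameter count.
#' @export
ann_param_count <- function(n_hidden, n_outputs = 37) {
  as.integer(2 * n_hidden + n_hidden + n_outputs * n_hidden + n_outputs)
}

#' Build an untrained dissolution ANN
#'
#' Two inputs (mean HPMC concentration in w/w %, HPMC particle size in um),
#' one hidden layer of 1-10 hyperbolic-tangent units, 37 linear outputs (one
#' per point of the dissolution schedule). Weights are randomly initialized,
#' reproducibly per seed; inputs and outputs are z-scored by the training
#' statistics (stored in the model) to avoid tanh saturation.
#'
#' @param n_hidden hidden units, in 1-10.
#' @param seed initialization seed.
#' @param times the output time grid (default the 37-point schedule).
#' @return an `ann_model`.
#' @export
build_ann <- function(n_hidden, seed = 1, times = dissolution_times()) {
  if (!is.numeric(n_hidden) || n_hidden < 1 || n_hidden > 10 ||
      n_hidden != round(n_hidden)) {
    stop("invalid-configuration: n_hidden must be an integer in 1-10",
         call. = FALSE)
  }
  n_hidden <- as.integer(n_hidden)
  n_out <- length(times)
  set.seed(seed)
  structure(list(
    n_hidden = n_hidden, n_out = n_out, times = times,
    W1 = matrix(rnorm(n_hidden * 2, 0, 0.5), n_hidden, 2),
    b1 = rnorm(n_hidden, 0, 0.5),
    W2 = matrix(rnorm(n_out * n_hidden, 0, 0.5), n_out, n_hidden),
    b2 = rnorm(n_out, 0, 0.5),
    input_scaler = NULL, output_scaler = NULL, trained = FALSE, seed = seed
  ), class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> 2 -> %d (tanh) -> %d (linear), %d parameters%s\n",
              x$n_hidden, x$n_out, ann_param_count(x$n_hidden, x$n_out),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

ann_pack <- function(m) c(as.numeric(m$W1), m$b1, as.numeric(m$W2), m$b2)

ann_unpack <- function(m, w) {
  h <- m$n_hidden
  o <- m$n_out
  i <- 0
  m$W1 <- matrix(w[i + seq_len(2 * h)], h, 2); i <- i + 2 * h
  m$b1 <- w[i + seq_len(h)]; i <- i + h
  m$W2 <- matrix(w[i + seq_len(o * h)], o, h); i <- i + o * h
  m$b2 <- w[i + seq_len(o)]
  m
}

# Forward pass on standardized inputs. Xz: N x 2. Returns predictions (N x o)
# and hidden activations (N x h).
ann_forward_std <- function(m, Xz) {
  A <- tanh(Xz %*% t(m$W1) + matrix(m$b1, nrow(Xz), m$n_hidden, byrow = TRUE))
  Y <- A %*% t(m$W2) + matrix(m$b2, nrow(Xz), m$n_out, byrow = TRUE)
  list(Y = Y, A = A)
}

# Gradient of Ed = 0.5 * sum(E^2) with respect to the packed parameters,
# computed in closed form (no explicit Jacobian).
ann_grad_ed <- function(m, Xz, A, E) {
  Da <- 1 - A^2
  S <- (E %*% m$W2) * Da # N x h
  gW1 <- crossprod(S, Xz) # h x 2
  gb1 <- colSums(S)
  gW2 <- crossprod(E, A) # o x h
  gb2 <- colSums(E)
  c(as.numeric(gW1), gb1, as.numeric(gW2), gb2)
}

# Gauss-Newton matrix J'J of the residual Jacobian, assembled blockwise from
# the network structure: hidden-side columns couple through W2'W2, output-
# side columns are block-diagonal over outputs (each output neuron owns its
# row of W2 and its bias). Equals crossprod(ann_jacobian(...)) exactly.
ann_gauss_newton <- function(m, Xz, A) {
  N <- nrow(Xz)
  h <- m$n_hidden
  o <- m$n_out
  P <- ann_param_count(h, o)
  Da <- 1 - A^2
  Z <- cbind(Xz, 1) # N x 3: input 1, input 2, hidden bias
  W2tW2 <- crossprod(m$W2) # h x h
  DZ <- lapply(1:3, function(k) Da * Z[, k]) # each N x h

  H <- matrix(0, P, P)
  # theta1 = (W1[,1], W1[,2], b1) blocks: (W2'W2) o C_kk'
  for (k in 1:3) {
    for (kp in k:3) {
      B <- W2tW2 * crossprod(DZ[[k]], DZ[[kp]])
      ri <- (k - 1) * h + seq_len(h)
      ci <- (kp - 1) * h + seq_len(h)
      H[ri, ci] <- B
      if (kp > k) H[ci, ri] <- t(B)
    }
  }
  # theta1 x W2 blocks: for hidden unit j2 (columns (j2-1)*o + 1:o),
  # entry ((k,j), (j2,oo)) = M_k[j, j2] * W2[oo, j]
  tW2 <- t(m$W2) # h x o
  for (k in 1:3) {
    Mk <- crossprod(DZ[[k]], A) # h x h
    ri <- (k - 1) * h + seq_len(h)
    for (j2 in seq_len(h)) {
      B <- Mk[, j2] * tW2 # h x o, row-scaled
      ci <- 3 * h + (j2 - 1) * o + seq_len(o)
      H[ri, ci] <- B
      H[ci, ri] <- t(B)
    }
    # theta1 x b2: entry ((k,j), oo) = v_k[j] * W2[oo, j]
    vk <- colSums(DZ[[k]])
    B <- vk * tW2
    ci <- 3 * h + h * o + seq_len(o)
    H[ri, ci] <- B
    H[ci, ri] <- t(B)
  }
  # W2 x W2: Gram[j,j'] on the diagonal over outputs
  Gram <- crossprod(A) # h x h
  io <- diag(o)
  ci0 <- 3 * h
  H[ci0 + seq_len(h * o + o), ci0 + seq_len(h * o + o)] <-
    rbind(cbind(kronecker(Gram, io), kronecker(matrix(colSums(A), h, 1), io)),
          cbind(kronecker(matrix(colSums(A), 1, h), io), N * io))
  H
}

# Explicit Jacobian of the stacked residual vector vec(Yhat - Y) (output
# fastest, then samples) with respect to the packed parameter vector. O(N*o*P)
# memory — used as the correctness oracle for the structured path above and
# for small problems.
ann_jacobian <- function(m, Xz, A) {
  N <- nrow(Xz)
  h <- m$n_hidden
  o <- m$n_out
  P <- ann_param_count(h, o)
  J <- matrix(0, N * o, P)
  d_a <- 1 - A^2 # N x h
  for (i in seq_len(N)) {
    rows <- (i - 1) * o + seq_len(o)
    # d y_o / d W1[j,k] = W2[o,j] * (1 - a_j^2) * x_k
    g <- m$W2 * matrix(d_a[i, ], o, h, byrow = TRUE) # o x h
    J[rows, seq_len(2 * h)] <- cbind(g * Xz[i, 1], g * Xz[i, 2])
    J[rows, 2 * h + seq_len(h)] <- g
    # d y_o / d W2[o,j] = a_j (block structure over outputs)
    for (j in seq_len(h)) {
      J[cbind(rows, 3 * h + (j - 1) * o + seq_len(o))] <- A[i, j]
    }
    J[cbind(rows, 3 * h + h * o + seq_len(o))] <- 1
  }
  J
}

#' Train a dissolution ANN with Bayesian-regularized Levenberg-Marquardt
#'
#' Minimizes `F = beta * Ed + alpha * Ew` (`Ed` half the summed squared
#' residuals in standardized units, `Ew` half the squared weight norm) by
#' Levenberg-Marquardt, with MacKay evidence updates of the hyperparameters
#' after every accepted step: effective parameter number
#' `gamma = P - 2 alpha tr(H^-1)`, `alpha = gamma / (2 Ew)`,
#' `beta = (N_obs - gamma) / (2 Ed)`. Training stops at `max_epochs`, when
#' the objective-gradient infinity norm falls below `grad_tol`, or when the
#' damping parameter mu exceeds `mu_max`.
#'
#' @param model a [build_ann()] model.
#' @param X numeric N x 2 matrix: (mean HPMC concentration w/w %, particle
#'   size um).
#' @param Y numeric N x 37 matrix of release percentages on the model's time
#'   grid.
#' @param max_epochs epoch cap (default 1000).
#' @param grad_tol gradient stopping tolerance (default 1e-7).
#' @param mu0,mu_max initial / maximal LM damping.
#' @param regularization `"bayes"` (evidence updates) or `"none"` (plain LM
#'   on the unregularized MSE path, alpha fixed at 0).
#' @return the trained model with `history` (alpha, beta, gamma, Ed, Ew, mu,
#'   objective per epoch) and `termination` (reason string) attached.
#' @export
train_bayesreg <- function(model, X, Y, max_epochs = 1000, grad_tol = 1e-7,
                           mu0 = 0.005, mu_max = 1e10,
                           regularization = c("bayes", "none")) {
  stopifnot(inherits(model, "ann_model"))
  regularization <- match.arg(regularization)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(ncol(X) == 2, ncol(Y) == model$n_out, nrow(X) == nrow(Y))
  N <- nrow(X)
  P <- ann_param_count(model$n_hidden, model$n_out)
  if (N < P / 10) {
    warning("fewer than n_parameters / 10 samples; fit may be unstable",
            call. = FALSE)
  }

  xm <- colMeans(X); xs <- apply(X, 2, sd)
  xs[!is.finite(xs) | xs < 1e-12] <- 1
  ym <- colMeans(Y); ys <- apply(Y, 2, sd)
  ys[!is.finite(ys) | ys < 1e-12] <- 1
  model$input_scaler <- list(mean = xm, sd = xs)
  model$output_scaler <- list(mean = ym, sd = ys)
  Xz <- sweep(sweep(X, 2, xm), 2, xs, `/`)
  Yz <- sweep(sweep(Y, 2, ym), 2, ys, `/`)

  w <- ann_pack(model)
  n_obs <- N * model$n_out
  alpha <- if (regularization == "bayes") 0 else 0
  beta <- 1
  gamma <- P
  mu <- mu0

  objective <- function(wv) {
    mm <- ann_unpack(model, wv)
    fw <- ann_forward_std(mm, Xz)
    E <- fw$Y - Yz
    Ed <- 0.5 * sum(E^2)
    Ew <- 0.5 * sum(wv^2)
    list(E = E, Ed = Ed, Ew = Ew, F = beta * Ed + alpha * Ew, A = fw$A,
         model = mm)
  }

  cur <- objective(w)
  hist <- list()
  reason <- "max_epochs"
  epochs_used <- 0L
  any_accepted <- FALSE
  for (epoch in seq_len(max_epochs)) {
    epochs_used <- epoch
    g <- beta * ann_grad_ed(cur$model, Xz, cur$A, cur$E) + alpha * w
    if (max(abs(g)) < grad_tol) {
      reason <- "min_grad"
      epochs_used <- epoch - 1L
      break
    }
    JtJ <- ann_gauss_newton(cur$model, Xz, cur$A)
    accepted <- FALSE
    while (!accepted) {
      Hd <- beta * JtJ
      diag(Hd) <- diag(Hd) + alpha + mu
      step <- tryCatch(solve(Hd, -g), error = function(e) NULL)
      if (!is.null(step)) {
        w_try <- w + as.numeric(step)
        try_obj <- objective(w_try)
        if (is.finite(try_obj$F) && try_obj$F < cur$F) {
          accepted <- TRUE
          w <- w_try
          cur <- try_obj
          mu <- max(mu / 10, 1e-20)
          break
        }
      }
      mu <- mu * 10
      if (mu > mu_max) break
    }
    if (!accepted) {
      if (!any_accepted) {
        stop("training-failed: Levenberg-Marquardt damping exhausted before any progress",
             call. = FALSE)
      }
      reason <- "mu_max"
      break
    }
    any_accepted <- TRUE
    if (regularization == "bayes") {
      Hreg <- beta * JtJ
      diag(Hreg) <- diag(Hreg) + alpha
      trinv <- tryCatch(sum(diag(chol2inv(chol(Hreg)))),
                        error = function(e) NA_real_)
      if (is.finite(trinv)) {
        gamma <- P - 2 * alpha * trinv
        gamma <- min(max(gamma, 1e-6), P)
        alpha <- gamma / max(2 * cur$Ew, 1e-12)
        beta <- max(n_obs - gamma, 1e-6) / max(2 * cur$Ed, 1e-12)
        cur$F <- beta * cur$Ed + alpha * cur$Ew
      }
    }
    hist[[epoch]] <- c(epoch = epoch, alpha = alpha, beta = beta,
                       gamma = gamma, Ed = cur$Ed, Ew = cur$Ew, mu = mu,
                       objective = cur$F)
  }

  model <- cur$model
  model$input_scaler <- list(mean = xm, sd = xs)
  model$output_scaler <- list(mean = ym, sd = ys)
  model$trained <- TRUE
  model$history <- as.data.frame(do.call(rbind, hist))
  model$termination <- reason
  model$epochs_used <- epochs_used
  model$final_alpha <- alpha
  model$final_beta <- beta
  model$final_gamma <- gamma
  model
}

#' Predict a dissolution profile
#'
#' Feeds the standardized (concentration, size) pair through the trained
#' network, de-standardizes the 37 outputs and clamps them to `[0, 110]`
#' (mild overshoot allowed; no monotonicity forcing — raw network outputs are
#' reported).
#'
#' @param model a trained [train_bayesreg()] model.
#' @param concentration mean HPMC concentration in w/w %.
#' @param size HPMC particle size in um.
#' @return a [dissolution_profile()] on the model's time grid.
#' @export
predict_profile <- function(model, concentration, size) {
  stopifnot(inherits(model, "ann_model"))
  if (!model$trained) stop("not-fitted: train the ANN first", call. = FALSE)
  x <- c(concentration, size)
  xz <- (x - model$input_scaler$mean) / model$input_scaler$sd
  out <- ann_forward_std(model, matrix(xz, 1))$Y[1, ]
  out <- out * model$output_scaler$sd + model$output_scaler$mean
  dissolution_profile(model$times, pmin(pmax(out, 0), 110))
}

#' Train an ensemble of dissolution ANNs and select the best by validation f2
#'
#' For every hidden-layer width in `hidden_range`, `runs` networks are
#' trained from different random initializations; each is scored by the mean
#' f2 similarity factor (with the 85% truncation rule) of its predictions
#' over the validation tablets, and the best-scoring model is returned with
#' the full score table. A failed run scores `-Inf`.
#'
#' @param Xtrain,Ytrain training inputs (N x 2) and profiles (N x 37).
#' @param Xval validation inputs (M x 2).
#' @param Yval_profiles list of M measured [dissolution_profile()]s.
#' @param runs restarts per hidden width (100 at full protocol scale; 10 is
#'   the desk-scale default).
#' @param hidden_range hidden widths to scan (subset of 1-10).
#' @param master_seed seed from which one seed per (width, run) derives.
#' @param max_epochs,grad_tol passed to [train_bayesreg()].
#' @param times output time grid.
#' @return a `selection_result`: `best_model`, `best_n_hidden`, `best_run`,
#'   `best_score`, `scores` data frame (n_hidden, run, mean_f2).
#' @export
train_ensemble <- function(Xtrain, Ytrain, Xval, Yval_profiles, runs = 10,
                           hidden_range = 1:10, master_seed = 1,
                           max_epochs = 1000, grad_tol = 1e-7,
                           times = dissolution_times()) {
  stopifnot(length(Yval_profiles) >= 1, nrow(as.matrix(Xval)) ==
              length(Yval_profiles))
  Xval <- as.matrix(Xval)
  scores <- expand.grid(run = seq_len(runs), n_hidden = hidden_range)
  scores <- scores[, c("n_hidden", "run")]
  scores$mean_f2 <- NA_real_
  best <- list(score = -Inf, model = NULL, n_hidden = NA, run = NA)
  for (r in seq_len(nrow(scores))) {
    h <- scores$n_hidden[r]
    run <- scores$run[r]
    seed <- derive_seed(master_seed, h * 1000 + run)
    fit <- tryCatch({
      m <- build_ann(h, seed = seed, times = times)
      m <- train_bayesreg(m, Xtrain, Ytrain, max_epochs = max_epochs,
                          grad_tol = grad_tol)
      f2s <- vapply(seq_along(Yval_profiles), function(i) {
        pred <- predict_profile(m, Xval[i, 1], Xval[i, 2])
        f2(truncate_at_85(profile_pair(Yval_profiles[[i]], pred)))
      }, numeric(1))
      list(score = mean(f2s), model = m)
    }, error = function(e) list(score = -Inf, model = NULL))
    if (!is.null(fit$model) && fit$score > best$score) {
      best <- list(score = fit$score, model = fit$model, n_hidden = h,
                   run = run)
    }
    scores$mean_f2[r] <- fit$score
  }
  if (is.null(best$model)) {
    stop("training-failed: every ensemble member failed", call. = FALSE)
  }
  structure(list(best_model = best$model, best_n_hidden = best$n_hidden,
                 best_run = best$run, best_score = best$score,
                 scores = scores), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> best: %d hidden units (run %d), mean validation f2 = %.2f over %d configs\n",
              x$best_n_hidden, x$best_run, x$best_score, nrow(x$scores)))
  invisible(x)
}
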