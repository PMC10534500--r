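# Small convolutional network regressing HPMC particle size (the upper sieve
# pore size, um) from a single-channel concentration map. Implemented from
# scratch (im2col convolutions, batch normalization, average pooling, Adam)
# because no deep-learning backend is assumed; the networks involved are tiny.

# ---- layer plumbing ---------------------------------------------------------
#
# Feature maps are carried as flat matrices of shape (H*W*N) x C — spatial
# position fastest, then sample, channels in columns. This keeps convolution
# (im2col + matmul), batch normalization (column statistics) and pooling
# (precomputed row gathers) free of array transposes, which dominate the cost
# otherwise.

# Precomputed geometry of one conv + pool block: im2col gather template into
# the zero-padded plane, pool gather template, and a per-batch-size cache.
conv_ctx <- function(H, W, Cin, k = 3, pool = 2) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  pad_pos <- (ii + p) + (jj + p - 1L) * Hp
  idx9 <- matrix(0L, H * W, k * k)
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      idx9[, (dj - 1L) * k + di] <- (ii + di - 1L) + (jj + dj - 2L) * Hp
    }
  }
  Ho <- H %/% pool
  Wo <- W %/% pool
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  pool_idx <- matrix(0L, Ho * Wo, pool * pool)
  for (dj in seq_len(pool)) {
    for (di in seq_len(pool)) {
      pool_idx[, (dj - 1L) * pool + di] <-
        ((oi - 1L) * pool + di) + ((oj - 1L) * pool + dj - 1L) * H
    }
  }
  list(H = H, W = W, Cin = Cin, k = k, pad = p, Hp = Hp, Wp = Wp,
       HW = H * W, plane = Hp * Wp, pad_pos = pad_pos, idx9 = idx9,
       pool = pool, Ho = Ho, Wo = Wo, pool_idx = pool_idx,
       cache = new.env(parent = emptyenv()))
}

# Batch-size-specific gather indices, memoized per ctx.
ctx_batch <- function(ctx, N) {
  key <- as.character(N)
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  HW <- ctx$HW
  offs <- rep((seq_len(N) - 1L) * ctx$plane, each = HW)
  pad_rows <- rep(ctx$pad_pos, times = N) + offs
  idx9_big <- ctx$idx9[rep(seq_len(HW), times = N), , drop = FALSE] + offs
  HWo <- ctx$Ho * ctx$Wo
  offs_o <- rep((seq_len(N) - 1L) * HW, each = HWo)
  pool_big <- ctx$pool_idx[rep(seq_len(HWo), times = N), , drop = FALSE] +
    offs_o
  val <- list(pad_rows = pad_rows, idx9_big = idx9_big, pool_big = pool_big,
              N = N)
  ctx$cache[[key]] <- val
  val
}

conv_forward <- function(M, Wf, b, ctx, cb) {
  k2 <- ctx$k^2
  Mpad <- matrix(0, ctx$plane * cb$N, ctx$Cin)
  Mpad[cb$pad_rows, ] <- M
  P <- matrix(0, ctx$HW * cb$N, k2 * ctx$Cin)
  for (c in seq_len(ctx$Cin)) {
    P[, (c - 1L) * k2 + seq_len(k2)] <- Mpad[, c][cb$idx9_big]
  }
  Y <- P %*% Wf
  Y <- Y + rep(b, each = nrow(Y))
  list(out = Y, P = P)
}

conv_backward <- function(dY, Wf, P, ctx, cb, compute_dx = TRUE) {
  db <- colSums(dY)
  dWf <- crossprod(P, dY)
  if (!compute_dx) return(list(dW = dWf, db = db, dX = NULL))
  # Input gradient of a stride-1 same-padded convolution is itself a
  # same-padded convolution of dY with the spatially flipped, channel-
  # transposed kernel — reuse the fast im2col path instead of scatter-adds.
  k2 <- ctx$k^2
  Cin <- ctx$Cin
  Cout <- ncol(Wf)
  Wflip <- matrix(0, k2 * Cout, Cin)
  for (c in seq_len(Cin)) {
    blk <- Wf[(c - 1L) * k2 + seq_len(k2), , drop = FALSE]
    Wflip[, c] <- as.numeric(blk[k2:1, , drop = FALSE])
  }
  Mpad <- matrix(0, ctx$plane * cb$N, Cout)
  Mpad[cb$pad_rows, ] <- dY
  P2 <- matrix(0, ctx$HW * cb$N, k2 * Cout)
  for (co in seq_len(Cout)) {
    P2[, (co - 1L) * k2 + seq_len(k2)] <- Mpad[, co][cb$idx9_big]
  }
  list(dW = dWf, db = db, dX = P2 %*% Wflip)
}

bn_forward <- function(Xm, gamma, beta, running, train, momentum = 0.9,
                       eps = 1e-5) {
  if (train) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    v[v < 0] <- 0
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Xm, 2, mu), 2, inv_sd, `*`)
  Ym <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = Ym, running = running,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma))
}

bn_backward <- function(dYm, cache) {
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dXm <- sweep(dYm, 2, colMeans(dYm)) -
    sweep(cache$xhat, 2, colMeans(dYm * cache$xhat), `*`)
  dXm <- sweep(dXm, 2, cache$gamma * cache$inv_sd, `*`)
  list(dX = dXm, dgamma = dgamma, dbeta = dbeta)
}

pool_forward <- function(M, cb) {
  np <- ncol(cb$pool_big)
  Y <- M[cb$pool_big[, 1], , drop = FALSE]
  for (q in 2:np) Y <- Y + M[cb$pool_big[, q], , drop = FALSE]
  Y / np
}

pool_backward <- function(dY, cb, n_rows_in) {
  np <- ncol(cb$pool_big)
  dX <- matrix(0, n_rows_in, ncol(dY))
  g <- dY / np
  for (q in seq_len(np)) dX[cb$pool_big[, q], ] <- g
  dX
}

# ---- model ------------------------------------------------------------------

#' Build the particle-size CNN
#'
#' Input `H x W x 1` concentration map; per block: same-padded convolution ->
#' ReLU -> dropout -> batch normalization -> average pooling; then a
#' fully-connected ReLU layer and a single linear regression output (particle
#' size). The default (two blocks of 16 filters, 3x3 kernels, dropout 0.2,
#' 32 fully-connected units) is the smallest architecture that plausibly
#' encodes blob-size statistics at 31 x 31 resolution. The default 4x4
#' average pooling collapses each block aggressively (31 -> 7 -> 1), so the
#' dense head stays tiny; with only 96 training maps a 2x2-pooled variant
#' keeps ~25k dense parameters and overfits badly (validation MAE roughly
#' doubles).
#'
#' @param input_shape integer `(H, W)`, both at least 8.
#' @param filters filter count per block (length = number of blocks).
#' @param kernel odd kernel size.
#' @param dropout_rate dropout probability in the training pass.
#' @param pool pooling factor per block.
#' @param fc_units fully-connected layer width.
#' @param seed seed for the weight initialization.
#' @return an untrained `particle_cnn` model.
#' @export
build_particle_cnn <- function(input_shape, filters = c(16, 16), kernel = 3,
                               dropout_rate = 0.2, pool = 4, fc_units = 32,
                               seed = 1) {
  H <- as.integer(input_shape[1])
  W <- as.integer(input_shape[2])
  if (H < 8 || W < 8) stop("input maps must be at least 8 x 8", call. = FALSE)
  if (kernel %% 2 != 1) stop("kernel size must be odd", call. = FALSE)
  n_blocks <- length(filters)
  dims <- list()
  h <- H; w <- W; cin <- 1L
  for (bkl in seq_len(n_blocks)) {
    dims[[bkl]] <- list(H = h, W = w, Cin = cin, Cout = filters[bkl])
    h <- h %/% pool
    w <- w %/% pool
    if (h < 1 || w < 1) {
      stop("invalid-architecture: pooling reduces a spatial dimension below 1",
           call. = FALSE)
    }
    cin <- filters[bkl]
  }
  flat <- h * w * cin

  set.seed(seed)
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)),
                                        nr, nc)
  params <- list(conv = list(), bn = list(),
                 fc = NULL, out = NULL)
  running <- list()
  ctxs <- list()
  for (bkl in seq_len(n_blocks)) {
    dmn <- dims[[bkl]]
    fan <- kernel^2 * dmn$Cin
    params$conv[[bkl]] <- list(W = he(fan, dmn$Cout, fan),
                               b = numeric(dmn$Cout))
    params$bn[[bkl]] <- list(gamma = rep(1, dmn$Cout),
                             beta = numeric(dmn$Cout))
    running[[bkl]] <- list(mean = numeric(dmn$Cout), var = rep(1, dmn$Cout))
    ctxs[[bkl]] <- conv_ctx(dmn$H, dmn$W, dmn$Cin, kernel, pool)
  }
  params$fc <- list(W = he(fc_units, flat, flat), b = numeric(fc_units))
  params$out <- list(W = he(1, fc_units, fc_units), b = 0)

  structure(list(
    input_shape = c(H, W), filters = filters, kernel = kernel,
    dropout_rate = dropout_rate, pool = pool, fc_units = fc_units,
    flat = flat, dims = dims, ctxs = ctxs, params = params,
    running = running, input_scaler = c(mean = 0, sd = 1),
    target_scaler = c(mean = 0, sd = 1), trained = FALSE, seed = seed
  ), class = "particle_cnn")
}

#' @export
print.particle_cnn <- function(x, ...) {
  cat(sprintf("<particle_cnn> %dx%d input, %s filters, %d parameters%s\n",
              x$input_shape[1], x$input_shape[2],
              paste(x$filters, collapse = "/"), cnn_param_count(x),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

#' Trainable parameter count of a particle CNN
#'
#' @param model a [build_particle_cnn()] model.
#' @return integer parameter count (a deterministic function of the
#'   architecture configuration).
#' @export
cnn_param_count <- function(model) {
  n <- 0L
  for (bkl in seq_along(model$params$conv)) {
    n <- n + length(model$params$conv[[bkl]]$W) +
      length(model$params$conv[[bkl]]$b) +
      length(model$params$bn[[bkl]]$gamma) +
      length(model$params$bn[[bkl]]$beta)
  }
  n + length(model$params$fc$W) + length(model$params$fc$b) +
    length(model$params$out$W) + 1L
}

# Coerce input to the flat (H*W*N) x 1 matrix plus N. Accepts (H, W, N) or
# (H, W, 1, N) arrays.
flatten_input <- function(X) {
  d <- dim(X)
  if (length(d) == 4) {
    N <- d[4]
  } else if (length(d) == 3) {
    N <- d[3]
  } else {
    stop("input must be an (H, W, N) or (H, W, 1, N) array", call. = FALSE)
  }
  list(M = matrix(as.numeric(X), ncol = 1), N = N)
}

# Full forward pass. X: standardized input array. In training mode dropout
# masks are drawn from the current RNG stream (or all-ones when the dropout
# rate is 0, making training deterministic given the seed).
cnn_forward <- function(model, X, train = FALSE) {
  fi <- flatten_input(X)
  M <- fi$M
  N <- fi$N
  caches <- list()
  running <- model$running
  for (bkl in seq_along(model$params$conv)) {
    ctx <- model$ctxs[[bkl]]
    cb <- ctx_batch(ctx, N)
    cv <- conv_forward(M, model$params$conv[[bkl]]$W,
                       model$params$conv[[bkl]]$b, ctx, cb)
    relu_mask <- cv$out > 0
    M <- cv$out * relu_mask
    if (train && model$dropout_rate > 0) {
      keep <- 1 - model$dropout_rate
      dmask <- matrix((runif(length(M)) < keep) / keep, nrow(M))
      M <- M * dmask
    } else {
      dmask <- NULL
    }
    bn <- bn_forward(M, model$params$bn[[bkl]]$gamma,
                     model$params$bn[[bkl]]$beta, running[[bkl]],
                     train = train)
    running[[bkl]] <- bn$running
    caches[[bkl]] <- list(P = cv$P, relu = relu_mask, drop = dmask,
                          bn = bn$cache, cb = cb, n_rows = nrow(M))
    M <- pool_forward(bn$out, cb)
  }
  # Flatten per sample for the dense head: (Ho*Wo*N) x C -> flat x N.
  last <- model$ctxs[[length(model$ctxs)]]
  HWo <- last$Ho * last$Wo
  C <- ncol(M)
  Fm <- matrix(aperm(array(M, c(HWo, N, C)), c(1, 3, 2)), model$flat, N)
  Z1 <- model$params$fc$W %*% Fm + model$params$fc$b
  relu_fc <- Z1 > 0
  A1 <- Z1 * relu_fc
  pred <- as.numeric(model$params$out$W %*% A1 + model$params$out$b)
  list(pred = pred, caches = caches, Fm = Fm, relu_fc = relu_fc, A1 = A1,
       running = running, N = N, HWo = HWo, C = C)
}

# Loss (MSE on standardized targets) and gradients for one batch.
cnn_loss_and_grads <- function(model, X, y, train = TRUE) {
  fw <- cnn_forward(model, X, train = train)
  N <- length(y)
  err <- fw$pred - y
  loss <- mean(err^2)
  dpred <- 2 * err / N

  g <- list(conv = list(), bn = list(), fc = NULL, out = NULL)
  dW_out <- matrix(dpred, 1) %*% t(fw$A1)
  db_out <- sum(dpred)
  dA1 <- t(model$params$out$W) %*% matrix(dpred, 1)
  dZ1 <- dA1 * fw$relu_fc
  g$out <- list(W = dW_out, b = db_out)
  g$fc <- list(W = dZ1 %*% t(fw$Fm), b = rowSums(dZ1))
  dF <- t(model$params$fc$W) %*% dZ1
  dM <- matrix(aperm(array(dF, c(fw$HWo, fw$C, N)), c(1, 3, 2)),
               fw$HWo * N, fw$C)

  for (bkl in rev(seq_along(model$params$conv))) {
    cc <- fw$caches[[bkl]]
    dM <- pool_backward(dM, cc$cb, cc$n_rows)
    bnb <- bn_backward(dM, cc$bn)
    g$bn[[bkl]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    dM <- bnb$dX
    if (!is.null(cc$drop)) dM <- dM * cc$drop
    dM <- dM * cc$relu
    cvb <- conv_backward(dM, model$params$conv[[bkl]]$W, cc$P,
                         model$ctxs[[bkl]], cc$cb, compute_dx = bkl > 1)
    g$conv[[bkl]] <- list(W = cvb$dW, b = cvb$db)
    dM <- cvb$dX
  }
  list(loss = loss, grads = g, running = fw$running)
}

# Recursive Adam update over the nested parameter structure.
adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0), how = "list")
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p) && !is.numeric(p)) {
      out_p <- p
      out_s <- s
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p
        out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      u <- upd(p, g, s)
      list(p = u$p, s = u$s)
    }
  }
  walk(params, grads, state)
}

#' Staircase learning-rate schedule
#'
#' `lr(e) = initial_lr * drop_factor ^ floor((e - 1) / drop_period)`.
#'
#' @param epoch epoch number (1-based).
#' @param initial_lr initial learning rate (default 0.001).
#' @param drop_period epochs between drops (default 10).
#' @param drop_factor multiplicative drop (default 0.9).
#' @return the learning rate at `epoch`.
#' @export
lr_schedule <- function(epoch, initial_lr = 0.001, drop_period = 10,
                        drop_factor = 0.9) {
  initial_lr * drop_factor^floor((epoch - 1) / drop_period)
}

#' CNN training configuration
#'
#' Defaults: Adam with initial learning rate 0.001, dropped by a factor 0.9
#' every 10 epochs, at most 100 epochs, validation loss evaluated every 5
#' epochs, batch size 16.
#'
#' @param initial_lr,lr_drop_period,lr_drop_factor staircase schedule.
#' @param max_epochs maximum epochs.
#' @param validation_every epochs between validation evaluations.
#' @param batch_size minibatch size.
#' @param seed training seed (shuffling, dropout).
#' @return a `cnn_train_config` list.
#' @export
cnn_train_config <- function(initial_lr = 0.001, lr_drop_period = 10,
                             lr_drop_factor = 0.9, max_epochs = 100,
                             validation_every = 5, batch_size = 16,
                             seed = 1) {
  stopifnot(initial_lr > 0, lr_drop_period > 0, lr_drop_factor > 0,
            max_epochs > 0, validation_every > 0, batch_size > 0)
  structure(list(initial_lr = initial_lr, lr_drop_period = lr_drop_period,
                 lr_drop_factor = lr_drop_factor,
                 max_epochs = as.integer(max_epochs),
                 validation_every = as.integer(validation_every),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cnn_train_config")
}

as_map_array <- function(maps) {
  if (is.list(maps)) {
    maps <- lapply(maps, function(m) if (inherits(m, "conc_map")) m$values
                   else m)
    arr <- array(0, c(nrow(maps[[1]]), ncol(maps[[1]]), length(maps)))
    for (i in seq_along(maps)) arr[, , i] <- maps[[i]]
    arr
  } else if (is.array(maps) && length(dim(maps)) == 3) {
    maps
  } else {
    stop("maps must be a list of matrices/conc_maps or an H x W x N array",
         call. = FALSE)
  }
}

#' Train the particle-size CNN
#'
#' Adam on mean squared error; inputs are standardized by the global training
#' pixel mean/sd and the size labels (um) are z-scored internally. The
#' learning rate follows [lr_schedule()]; the history records the per-epoch
#' training loss and the validation loss every `validation_every` epochs.
#'
#' When a validation set is supplied, the weights from the epoch with the
#' lowest validation loss are restored at the end (checkpoint selection);
#' with only 96 training maps this noticeably reduces the variance of the
#' final model.
#'
#' @param model a [build_particle_cnn()] model.
#' @param train_maps list of maps or `H x W x N` array.
#' @param train_labels size labels in um (45 / 63 / 100 / 150).
#' @param val_maps,val_labels optional validation set.
#' @param cfg a [cnn_train_config()].
#' @param restore_best restore the best-validation-loss checkpoint (ignored
#'   without a validation set).
#' @return the trained model, with a `history` data frame attached.
#' @export
train_particle_cnn <- function(model, train_maps, train_labels,
                               val_maps = NULL, val_labels = NULL,
                               cfg = cnn_train_config(),
                               restore_best = TRUE) {
  stopifnot(inherits(model, "particle_cnn"),
            inherits(cfg, "cnn_train_config"))
  Xtr <- as_map_array(train_maps)
  n <- dim(Xtr)[3]
  stopifnot(length(train_labels) == n)
  if (any(dim(Xtr)[1:2] != model$input_shape)) {
    stop("map shape does not match the model input", call. = FALSE)
  }
  mu <- mean(Xtr)
  sdev <- sd(as.numeric(Xtr))
  if (!is.finite(sdev) || sdev < 1e-12) sdev <- 1
  ym <- mean(train_labels)
  ys <- sd(train_labels)
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  model$input_scaler <- c(mean = mu, sd = sdev)
  model$target_scaler <- c(mean = ym, sd = ys)
  Xs <- (Xtr - mu) / sdev
  yz <- (train_labels - ym) / ys

  has_val <- !is.null(val_maps)
  if (has_val) {
    Xv <- (as_map_array(val_maps) - mu) / sdev
    yv <- (val_labels - ym) / ys
  }

  set.seed(cfg$seed)
  state <- adam_init(model$params)
  t_step <- 0L
  best_val <- Inf
  best_params <- NULL
  best_running <- NULL
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_val <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_schedule(epoch, cfg$initial_lr, cfg$lr_drop_period,
                      cfg$lr_drop_factor)
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      sel <- ord[start:min(start + cfg$batch_size - 1, n)]
      Xb <- Xs[, , sel, drop = FALSE]
      lg <- cnn_loss_and_grads(model, Xb, yz[sel], train = TRUE)
      if (!is.finite(lg$loss)) {
        stop(sprintf("training-diverged: non-finite loss at epoch %d", epoch),
             call. = FALSE)
      }
      model$running <- lg$running
      t_step <- t_step + 1L
      st <- adam_step(model$params, lg$grads, state, lr, t_step)
      model$params <- st$p
      state <- st$s
      batch_losses <- c(batch_losses, lg$loss)
    }
    vloss <- NA_real_
    if (has_val && (epoch %% cfg$validation_every == 0 ||
                    epoch == cfg$max_epochs)) {
      pv <- cnn_predict_std(model, Xv)
      vloss <- mean((pv - yv)^2)
      if (restore_best && vloss < best_val) {
        best_val <- vloss
        best_params <- model$params
        best_running <- model$running
      }
    }
    hist_epoch <- c(hist_epoch, epoch)
    hist_loss <- c(hist_loss, mean(batch_losses))
    hist_val <- c(hist_val, vloss)
  }
  if (!is.null(best_params)) {
    model$params <- best_params
    model$running <- best_running
  }
  model$trained <- TRUE
  model$history <- data.frame(epoch = hist_epoch, train_loss = hist_loss,
                              val_loss = hist_val)
  model
}

# Evaluation-mode forward in chunks (keeps im2col buffers small), on
# standardized (H, W, N) input; returns standardized predictions.
cnn_predict_std <- function(model, Xs, chunk = 32L) {
  N <- dim(Xs)[3]
  pred <- numeric(N)
  for (start in seq(1, N, by = chunk)) {
    sel <- start:min(start + chunk - 1L, N)
    pred[sel] <- cnn_forward(model, Xs[, , sel, drop = FALSE],
                             train = FALSE)$pred
  }
  pred
}

#' Predict HPMC particle size from a concentration map
#'
#' @param model a trained [train_particle_cnn()] model.
#' @param map a `conc_map`, matrix, or `H x W x N` array of maps.
#' @param clip clip predictions to this size range in um (the trained
#'   domain); `NULL` disables clipping.
#' @return predicted size(s) in um.
#' @export
predict_size <- function(model, map, clip = c(22.5, 200)) {
  stopifnot(inherits(model, "particle_cnn"))
  if (!model$trained) stop("not-fitted: train the CNN first", call. = FALSE)
  arr <- if (inherits(map, "conc_map")) {
    array(map$values, c(dim(map$values), 1))
  } else if (is.matrix(map)) {
    array(map, c(dim(map), 1))
  } else {
    as_map_array(map)
  }
  if (any(dim(arr)[1:2] != model$input_shape)) {
    stop("map shape does not match the model input", call. = FALSE)
  }
  Xs <- (arr - model$input_scaler[["mean"]]) / model$input_scaler[["sd"]]
  pred <- cnn_predict_std(model, Xs)
  pred <- pred * model$target_scaler[["sd"]] + model$target_scaler[["mean"]]
  if (!is.null(clip)) pred <- pmin(pmax(pred, clip[1]), clip[2])
  pred
}

#' Stratified train / validation split
#'
#' Splits record indices into disjoint, exhaustive train and validation sets,
#' allocating validation picks by cycling over the strata (e.g. HPMC level x
#' size fraction) as far as divisibility allows. Deterministic per seed.
#'
#' @param strata data frame (one row per record) whose column combination
#'   defines the strata, or a vector of stratum labels.
#' @param n_val validation size, `< nrow(strata)`.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `val`.
#' @export
split_train_val <- function(strata, n_val, seed = 1) {
  if (is.data.frame(strata)) {
    labels <- interaction(strata, drop = TRUE)
  } else {
    labels <- factor(strata)
  }
  n <- length(labels)
  if (n_val >= n) {
    stop("invalid-configuration: n_val must be smaller than the dataset",
         call. = FALSE)
  }
  set.seed(seed)
  by_stratum <- split(seq_len(n), labels)
  by_stratum <- lapply(by_stratum, function(ix) ix[sample.int(length(ix))])
  ord <- sample(names(by_stratum))
  val <- integer(0)
  while (length(val) < n_val) {
    for (nm in ord) {
      if (length(val) >= n_val) break
      if (length(by_stratum[[nm]]) > 0) {
        val <- c(val, by_stratum[[nm]][1])
        by_stratum[[nm]] <- by_stratum[[nm]][-1]
      }
    }
  }
  val <- sort(val)
  list(train = setdiff(seq_len(n), val), val = val)
}
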