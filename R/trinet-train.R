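# TriNet training engine ------------------------------------------------------
#
# Batched forward/backward passes and mini-batch gradient descent for the
# three branches. The selected feature vector is presented to the recurrent
# branches as a length-d sequence of scalars and to the CNN branch as a 1-D
# signal. Gradients are hand-derived (softmax cross-entropy head, BPTT for
# the gated cell, routing through ReLU and max-pool for the CNN) and checked
# against central finite differences in the test suite.

N_CLASSES <- 3L

# --- batched gated cell (shared by the LSTM and gated-RNN branches) ---------
# Combined weights: W is (H + 1) x 4H with gate column blocks [i | f | g | o];
# input at each step is one scalar feature.

init_recurrent_branch <- function(hidden, scale = 0.2) {
  H <- hidden
  W <- matrix(runif((H + 1) * 4 * H, -scale, scale), H + 1, 4 * H)
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1          # forget-gate bias: remember by default
  list(W = W, b = b,
       w_out = matrix(runif(H * N_CLASSES, -scale, scale), H, N_CLASSES),
       b_out = rep(0, N_CLASSES), hidden = H)
}

recurrent_forward_batch <- function(x, br, keep_cache = FALSE) {
  n <- nrow(x); d <- ncol(x); H <- br$hidden
  h <- matrix(0, n, H); c_st <- matrix(0, n, H)
  cache <- if (keep_cache) vector("list", d) else NULL
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_g <- (2 * H + 1):(3 * H); idx_o <- (3 * H + 1):(4 * H)
  for (t in seq_len(d)) {
    inp <- cbind(h, x[, t])
    z <- inp %*% br$W
    z <- sweep(z, 2, br$b, "+")
    i_g <- sigmoid(z[, idx_i, drop = FALSE])
    f_g <- sigmoid(z[, idx_f, drop = FALSE])
    g <- tanh(z[, idx_g, drop = FALSE])
    o_g <- sigmoid(z[, idx_o, drop = FALSE])
    c_prev <- c_st
    c_st <- f_g * c_prev + i_g * g
    tc <- tanh(c_st)
    h <- o_g * tc
    if (keep_cache) {
      cache[[t]] <- list(inp = inp, i = i_g, f = f_g, g = g, o = o_g,
                         c_prev = c_prev, tc = tc)
    }
  }
  logits <- sweep(h %*% br$w_out, 2, br$b_out, "+")
  list(h = h, logits = logits, probs = softmax(logits), cache = cache)
}

recurrent_backward_batch <- function(x, y01, fw, br) {
  n <- nrow(x); d <- ncol(x); H <- br$hidden
  dlogits <- (fw$probs - y01) / n
  g_wout <- t(fw$h) %*% dlogits
  g_bout <- colSums(dlogits)
  dh <- dlogits %*% t(br$w_out)
  dc <- matrix(0, n, H)
  gW <- matrix(0, nrow(br$W), ncol(br$W))
  gb <- rep(0, length(br$b))
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_g <- (2 * H + 1):(3 * H); idx_o <- (3 * H + 1):(4 * H)
  for (t in rev(seq_len(d))) {
    cc <- fw$cache[[t]]
    do_g <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_g * cc$o * (1 - cc$o))
    gW <- gW + t(cc$inp) %*% dz
    gb <- gb + colSums(dz)
    dinp <- dz %*% t(br$W)
    dh <- dinp[, seq_len(H), drop = FALSE]
    dc <- dc * cc$f
  }
  list(W = gW, b = gb, w_out = g_wout, b_out = g_bout)
}

# --- batched 1-D CNN branch --------------------------------------------------

init_cnn_branch <- function(input_len, n_filters = 8L, kernel = 3L,
                            pool = 2L, stride = 2L, padding = 0L,
                            dropout = 0, scale = 0.2) {
  kernel <- min(kernel, input_len + 2L * padding)
  conv_len <- input_len + 2L * padding - kernel + 1L
  pool <- min(pool, conv_len)
  pooled_len <- (conv_len - pool) %/% stride + 1L
  list(kernels = matrix(runif(kernel * n_filters, -scale, scale),
                        kernel, n_filters),
       bias = rep(0, n_filters),
       w_out = matrix(runif(pooled_len * n_filters * N_CLASSES, -scale, scale),
                      pooled_len * n_filters, N_CLASSES),
       b_out = rep(0, N_CLASSES),
       kernel = kernel, n_filters = n_filters, pool = pool, stride = stride,
       padding = padding, dropout = dropout,
       conv_len = conv_len, pooled_len = pooled_len)
}

cnn_forward_batch <- function(x, br, keep_cache = FALSE, train = FALSE) {
  n <- nrow(x)
  if (br$padding > 0) {
    x <- cbind(matrix(0, n, br$padding), x, matrix(0, n, br$padding))
  }
  k <- br$kernel; L <- br$conv_len; nf <- br$n_filters
  z <- array(0, c(n, L, nf))
  for (l in seq_len(k)) {
    xl <- x[, l:(l + L - 1L), drop = FALSE]
    for (f in seq_len(nf)) {
      z[, , f] <- z[, , f] + xl * br$kernels[l, f]
    }
  }
  for (f in seq_len(nf)) z[, , f] <- z[, , f] + br$bias[f]
  a <- array(pmax(z, 0), dim(z))
  Lp <- br$pooled_len
  pooled <- array(-Inf, c(n, Lp, nf))
  argmax <- array(1L, c(n, Lp, nf))
  for (w in seq_len(Lp)) {
    s <- (w - 1L) * br$stride
    for (off in seq_len(br$pool)) {
      cand <- a[, s + off, , drop = FALSE]
      cur <- pooled[, w, , drop = FALSE]
      upd <- cand > cur
      cur[upd] <- cand[upd]
      pooled[, w, ] <- cur
      am <- argmax[, w, , drop = FALSE]
      am[upd] <- off
      argmax[, w, ] <- am
    }
  }
  flat <- pooled
  dim(flat) <- c(n, Lp * nf)
  drop_mask <- NULL
  if (train && br$dropout > 0) {
    drop_mask <- matrix(runif(length(flat)) >= br$dropout, nrow(flat)) /
      (1 - br$dropout)
    flat <- flat * drop_mask
  }
  logits <- sweep(flat %*% br$w_out, 2, br$b_out, "+")
  out <- list(logits = logits, probs = softmax(logits))
  if (keep_cache) {
    out$cache <- list(x_pad = x, z = z, argmax = argmax, flat = flat,
                      drop_mask = drop_mask)
  }
  out
}

cnn_backward_batch <- function(y01, fw, br) {
  cc <- fw$cache
  n <- nrow(fw$probs)
  dlogits <- (fw$probs - y01) / n
  g_wout <- t(cc$flat) %*% dlogits
  g_bout <- colSums(dlogits)
  dflat <- dlogits %*% t(br$w_out)
  if (!is.null(cc$drop_mask)) dflat <- dflat * cc$drop_mask
  Lp <- br$pooled_len; nf <- br$n_filters; L <- br$conv_len
  dpool <- dflat
  dim(dpool) <- c(n, Lp, nf)
  da <- array(0, c(n, L, nf))
  for (w in seq_len(Lp)) {
    s <- (w - 1L) * br$stride
    for (off in seq_len(br$pool)) {
      mask <- cc$argmax[, w, , drop = FALSE] == off
      contrib <- dpool[, w, , drop = FALSE] * mask
      da[, s + off, ] <- da[, s + off, ] + contrib[, 1, ]
    }
  }
  dz <- da * (cc$z > 0)
  g_k <- matrix(0, br$kernel, nf)
  g_b <- numeric(nf)
  for (f in seq_len(nf)) {
    g_b[f] <- sum(dz[, , f])
    for (l in seq_len(br$kernel)) {
      xl <- cc$x_pad[, l:(l + L - 1L), drop = FALSE]
      g_k[l, f] <- sum(xl * dz[, , f])
    }
  }
  list(kernels = g_k, bias = g_b, w_out = g_wout, b_out = g_bout)
}

# --- training ----------------------------------------------------------------

cross_entropy <- function(probs, y01) {
  -mean(rowSums(y01 * log(pmax(probs, 1e-12))))
}

onehot <- function(y) {
  m <- matrix(0, length(y), N_CLASSES)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

sgd_update <- function(br, grads, lr) {
  for (nm in names(grads)) br[[nm]] <- br[[nm]] - lr * grads[[nm]]
  br
}

train_branch <- function(x, y01, br, kind, epochs, batch_size, lr) {
  n <- nrow(x)
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y01[idx, , drop = FALSE]
      if (kind == "cnn") {
        fw <- cnn_forward_batch(xb, br, keep_cache = TRUE, train = TRUE)
        grads <- cnn_backward_batch(yb, fw, br)
      } else {
        fw <- recurrent_forward_batch(xb, br, keep_cache = TRUE)
        grads <- recurrent_backward_batch(xb, yb, fw, br)
      }
      losses <- c(losses, cross_entropy(fw$probs, yb))
      br <- sgd_update(br, grads, lr)
    }
    loss_hist[ep] <- mean(losses)
  }
  list(branch = br, loss = loss_hist)
}

#' TriNet training configuration
#'
#' @param epochs Training epochs per branch (at least 1).
#' @param batch_size Mini-batch size for gradient descent.
#' @param lr Gradient-descent learning rate (step size).
#' @param hidden Hidden units of the LSTM and gated-RNN branches.
#' @param n_filters,kernel,pool,pool_stride,padding CNN branch shape.
#' @param dropout CNN dropout rate on the pooled layer during training.
#' @param fusion `"soft"` (average the branch probability vectors) or
#'   `"majority"` (one vote per branch; ties to the smallest class).
#' @param seed Integer seed; training is reproducible run-to-run.
#' @return A `trinet_config` list.
#' @export
trinet_config <- function(epochs = 50L, batch_size = 32L, lr = 0.1,
                          hidden = 8L, n_filters = 8L, kernel = 3L,
                          pool = 2L, pool_stride = 2L, padding = 0L,
                          dropout = 0, fusion = c("soft", "majority"),
                          seed = 1L) {
  fusion <- match.arg(fusion)
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, hidden >= 1)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, hidden = as.integer(hidden),
         n_filters = as.integer(n_filters), kernel = as.integer(kernel),
         pool = as.integer(pool), pool_stride = as.integer(pool_stride),
         padding = as.integer(padding), dropout = dropout,
         fusion = fusion, seed = seed),
    class = "trinet_config"
  )
}

#' Train the TriNet ensemble
#'
#' Trains the three branches — LSTM, 1-D CNN, and gated RNN — independently
#' by seeded mini-batch gradient descent on softmax cross-entropy. Features
#' are standardized internally (the scaler is stored on the model); each
#' standardized feature vector is presented to the recurrent branches as a
#' sequence of scalars and to the CNN branch as a 1-D signal.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Integer labels in 0:2; every class must be present.
#' @param config A [trinet_config()].
#' @return A `trinet_model` with the trained branches, the feature scaler,
#'   the fusion rule and per-branch loss histories.
#' @export
train_trinet <- function(x, y, config = trinet_config()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(0:2 %in% y)) {
    stopf("train_trinet(): all three classes must be present in `y`")
  }
  if (nrow(x) != length(y)) stopf("train_trinet(): x/y length mismatch")
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  y01 <- onehot(y)
  with_seed(config$seed, {
    lstm0 <- init_recurrent_branch(config$hidden)
    rnn0 <- init_recurrent_branch(config$hidden)
    cnn0 <- init_cnn_branch(ncol(xs), n_filters = config$n_filters,
                            kernel = config$kernel, pool = config$pool,
                            stride = config$pool_stride,
                            padding = config$padding,
                            dropout = config$dropout)
    lstm_tr <- train_branch(xs, y01, lstm0, "recurrent",
                            config$epochs, config$batch_size, config$lr)
    cnn_tr <- train_branch(xs, y01, cnn0, "cnn",
                           config$epochs, config$batch_size, config$lr)
    rnn_tr <- train_branch(xs, y01, rnn0, "recurrent",
                           config$epochs, config$batch_size, config$lr)
    structure(
      list(branches = list(lstm = lstm_tr$branch, cnn = cnn_tr$branch,
                           rnn = rnn_tr$branch),
           center = center, scale = scale_, fusion = config$fusion,
           config = config,
           loss_history = list(lstm = lstm_tr$loss, cnn = cnn_tr$loss,
                               rnn = rnn_tr$loss)),
      class = "trinet_model"
    )
  })
}

#' @export
print.trinet_model <- function(x, ...) {
  cat(sprintf("<trinet_model> %d features, fusion = %s\n",
              length(x$center), x$fusion))
  fl <- vapply(x$loss_history, function(l) l[length(l)], numeric(1))
  cat(sprintf("final training loss: lstm %.4f | cnn %.4f | rnn %.4f\n",
              fl["lstm"], fl["cnn"], fl["rnn"]))
  invisible(x)
}

# Per-branch class probabilities for a (raw, unstandardized) feature matrix.
trinet_branch_probs <- function(model, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  list(
    lstm = recurrent_forward_batch(xs, model$branches$lstm)$probs,
    cnn = cnn_forward_batch(xs, model$branches$cnn)$probs,
    rnn = recurrent_forward_batch(xs, model$branches$rnn)$probs
  )
}

#' Fused TriNet prediction
#'
#' Soft voting averages the three branch probability vectors and takes the
#' argmax; ties resolve to the smallest class index. Majority voting gives
#' each branch one vote (its own argmax) and falls back to the soft-vote
#' probabilities only through the same smallest-index tie rule.
#'
#' @param model A trained [train_trinet()] model.
#' @param x Feature matrix (or single feature vector).
#' @return List with `class` (integer vector, labels 0:2) and `probs`
#'   (fused probability matrix, rows summing to 1).
#' @export
fuse_predict <- function(model, x) {
  if (!inherits(model, "trinet_model")) stopf("fuse_predict(): untrained model")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  bp <- trinet_branch_probs(model, x)
  probs <- (bp$lstm + bp$cnn + bp$rnn) / 3
  cls <- if (model$fusion == "majority") {
    votes <- vapply(bp, function(p) max.col(p, ties.method = "first"),
                    integer(nrow(probs)))
    votes <- matrix(votes, nrow = nrow(probs))
    apply(votes, 1, function(v) {
      tab <- tabulate(v, nbins = N_CLASSES)
      which(tab == max(tab))[1]
    })
  } else {
    max.col(probs, ties.method = "first")
  }
  list(class = as.integer(cls - 1L), probs = probs)
}

#' Tune the CNN branch hyperparameters with HTLSS
#'
#' Minimizes validation misclassification of a short-budget CNN over the
#' hyperparameter box: filters in `[4, 64]`, kernel size in `[2, 7]`
#' (clamped to the input length), `log10` learning rate in `[-4, -1]`,
#' dropout in `[0, 0.5]`. Integer dimensions are rounded before each
#' evaluation. The best configuration is retrained at the full epoch budget.
#'
#' @param x_train,y_train Training data (labels 0:2, all classes present).
#' @param x_val,y_val Non-empty validation set scored by each candidate.
#' @param config An [hsstl_config()] for the 4-dimensional search (bounds
#'   are overridden to the hyperparameter box); defaults to a small budget.
#' @param space Hyperparameter box: list with `lo` and `up`, each length 4
#'   in the order (filters, kernel, log10 lr, dropout). A collapsed box
#'   (`lo == up`) degenerates to evaluating that single configuration.
#' @param short_epochs Epochs per fitness evaluation (default 10).
#' @param final_epochs Epochs for the final retrain (default 50).
#' @param seed Seed for every inner training run.
#' @return List with `hyper` (chosen values), `branch` (CNN branch retrained
#'   at full budget), `scaler`, `val_error`, and the optimizer `result`.
#' @export
optimize_cnn <- function(x_train, y_train, x_val, y_val, config = NULL,
                         space = list(lo = c(4, 2, -4, 0),
                                      up = c(64, 7, -1, 0.5)),
                         short_epochs = 10L, final_epochs = 50L, seed = 1L) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  if (nrow(x_val) == 0) stopf("optimize_cnn(): validation set is empty")
  lo <- space$lo
  up <- space$up
  if (is.null(config)) {
    config <- hsstl_config(dim = 4, lo = lo, up = up, pop_size = 8,
                           max_iters = 5, seed = seed)
  } else {
    config$dim <- 4L; config$lo <- lo; config$up <- up
  }
  center <- colMeans(x_train)
  scl <- apply(x_train, 2, sd); scl[scl == 0] <- 1
  xs_tr <- sweep(sweep(x_train, 2, center), 2, scl, "/")
  xs_val <- sweep(sweep(x_val, 2, center), 2, scl, "/")
  y01 <- onehot(as.integer(y_train))
  decode <- function(pos) {
    list(n_filters = as.integer(round(pos[1])),
         kernel = min(as.integer(round(pos[2])), ncol(xs_tr)),
         lr = 10^pos[3],
         dropout = pos[4])
  }
  fit_cnn <- function(hp, epochs) {
    with_seed(seed, {
      br <- init_cnn_branch(ncol(xs_tr), n_filters = hp$n_filters,
                            kernel = hp$kernel, pool = 2L, stride = 2L,
                            dropout = hp$dropout)
      train_branch(xs_tr, y01, br, "cnn", epochs,
                   batch_size = 32L, lr = hp$lr)$branch
    })
  }
  val_error <- function(br) {
    pred <- max.col(cnn_forward_batch(xs_val, br)$probs,
                    ties.method = "first") - 1L
    mean(pred != as.integer(y_val))
  }
  objective <- function(pos) val_error(fit_cnn(decode(pos), short_epochs))
  res <- run_hsstl(objective, config)
  hyper <- decode(res$best_position)
  branch <- fit_cnn(hyper, final_epochs)
  list(hyper = hyper, branch = branch,
       scaler = list(center = center, scale = scl),
       val_error = val_error(branch), result = res)
}
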