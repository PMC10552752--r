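test_that("LSTM forward matches the gate recurrences and a naive oracle", {
  H <- 3
  zero <- list(w_i = matrix(0, H, H + 1), w_f = matrix(0, H, H + 1),
               w_C = matrix(0, H, H + 1), w_o = matrix(0, H, H + 1),
               b_i = rep(0, H), b_f = rep(0, H), b_c = rep(0, H),
               b_o = rep(0, H))
  out <- lstm_forward(c(1, -2, 3), zero)
  expect_equal(out$c, matrix(0, 3, H))      # gates 0.5, candidate tanh(0) = 0
  expect_equal(out$h, matrix(0, 3, H))

  # forget gate saturated open, input gate shut: the cell is perfect memory
  mem <- zero
  mem$b_f <- rep(100, H)
  mem$b_i <- rep(-100, H)
  out <- lstm_forward(c(5, 5), mem, c0 = rep(1, H))
  expect_equal(out$c[2, ], rep(1, H), tolerance = 1e-12)

  set.seed(6)
  for (k in 1:20) {
    p <- random_lstm_params(H = 4, in_dim = 2)
    x <- rnorm(2)
    h0 <- rnorm(4); c0 <- rnorm(4)
    got <- lstm_forward(matrix(x, 1, 2), p, h0 = h0, c0 = c0)
    want <- lstm_step_oracle(x, h0, c0, p)
    expect_equal(got$h[1, ], want$h, tolerance = 1e-10)
    expect_equal(got$c[1, ], want$c, tolerance = 1e-10)
  }
  expect_error(lstm_forward(matrix(0, 2, 3), zero), "input dim")
})

test_that("the gated RNN branch is the LSTM recurrence under parameter mapping", {
  set.seed(7)
  p <- random_lstm_params(H = 3, in_dim = 1)
  rp <- list(u_ie = p$w_i, b_ie = p$b_i, u_fo = p$w_f, b_fo = p$b_f,
             u_og = p$w_o, b_og = p$b_o, u_i = p$w_C, b_i = p$b_c)
  seq_in <- rnorm(5)
  lout <- lstm_forward(seq_in, p)
  rout <- rnn_forward(seq_in, rp)
  expect_equal(rout$h, lout$h, tolerance = 1e-10)
  expect_equal(rout$cell, lout$c, tolerance = 1e-10)

  zero_r <- list(u_ie = matrix(0, 2, 3), b_ie = c(0, 0),
                 u_fo = matrix(0, 2, 3), b_fo = c(0, 0),
                 u_og = matrix(0, 2, 3), b_og = c(0, 0),
                 u_i = matrix(0, 2, 3), b_i = c(0, 0))
  expect_equal(rnn_forward(c(1, 2, 3), zero_r)$h, matrix(0, 3, 2))
  expect_equal(rnn_forward(c(3, 2, 1), zero_r)$h, matrix(0, 3, 2))
})

test_that("convolution, ReLU and max pooling follow their printed rules", {
  expect_equal(conv1d(c(1, 2, 3), c(1, 1)), c(3, 5))
  expect_equal(conv1d(c(1, 2, 3), c(1, 1), padding = 1), c(1, 3, 5, 3))
  expect_error(conv1d(c(1), c(1, 1)), "shorter than kernel")
  expect_equal(relu(c(-2, 2)), c(0, 2))
  expect_equal(maxpool1d(c(1, 3, 2, 5), pool = 2, stride = 2), c(3, 5))
  expect_equal(maxpool1d(c(1, 3, 2, 5, 4), pool = 2, stride = 1), c(3, 3, 5, 5))

  # 1-D path is the one-row specialization of the 2-D convolution
  set.seed(8)
  x <- rnorm(9); k <- rnorm(3)
  expect_equal(as.vector(conv2d(matrix(x, 1), matrix(k, 1))), conv1d(x, k))
})

test_that("the CNN head emits a probability vector over the 3 classes", {
  set.seed(9)
  br <- falldet:::init_cnn_branch(6, n_filters = 4, kernel = 3, pool = 2,
                                  stride = 2)
  params <- list(kernels = br$kernels, bias = br$bias, padding = br$padding,
                 pool = br$pool, stride = br$stride, w_out = br$w_out,
                 b_out = br$b_out)
  p <- cnn_forward(rnorm(6), params)
  expect_length(p, 3)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # agrees with the batched training engine
  x <- rnorm(6)
  pb <- falldet:::cnn_forward_batch(matrix(x, 1), br)$probs
  expect_equal(as.vector(pb), as.vector(cnn_forward(x, params)),
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  n <- 4; d <- 5
  x <- matrix(rnorm(n * d), n, d)
  y01 <- falldet:::onehot(sample(0:2, n, replace = TRUE))

  check_grads <- function(branch, fwd, bwd, par_names) {
    fw <- fwd(branch, keep = TRUE)
    gr <- bwd(branch, fw)
    worst <- 0
    for (nm in par_names) {
      for (i in seq_along(branch[[nm]])) {
        e <- 1e-5
        b1 <- branch; b2 <- branch
        b1[[nm]][i] <- b1[[nm]][i] + e
        b2[[nm]][i] <- b2[[nm]][i] - e
        num <- (falldet:::cross_entropy(fwd(b1)$probs, y01) -
                  falldet:::cross_entropy(fwd(b2)$probs, y01)) / (2 * e)
        an <- gr[[nm]][i]
        if (abs(num) > 1e-8 || abs(an) > 1e-8) {
          worst <- max(worst, abs(num - an) / max(abs(num), abs(an), 1e-8))
        }
      }
    }
    worst
  }

  rb <- falldet:::init_recurrent_branch(2)
  worst_r <- check_grads(
    rb,
    function(b, keep = FALSE) falldet:::recurrent_forward_batch(x, b, keep),
    function(b, fw) falldet:::recurrent_backward_batch(x, y01, fw, b),
    c("W", "b", "w_out", "b_out")
  )
  expect_lt(worst_r, 1e-4)

  cb <- falldet:::init_cnn_branch(d, n_filters = 3, kernel = 3, pool = 2,
                                  stride = 1)
  worst_c <- check_grads(
    cb,
    function(b, keep = FALSE) falldet:::cnn_forward_batch(x, b, keep),
    function(b, fw) falldet:::cnn_backward_batch(y01, fw, b),
    c("kernels", "bias", "w_out", "b_out")
  )
  expect_lt(worst_c, 1e-4)
})

test_that("training descends, is seed-deterministic, and requires all classes", {
  gen <- toy_separable(n_per_class = 30, seed = 5)
  cfg <- trinet_config(epochs = 20, seed = 5)
  m1 <- train_trinet(gen$x, gen$y, cfg)
  for (b in names(m1$loss_history)) {
    expect_lt(m1$loss_history[[b]][20], m1$loss_history[[b]][1])
  }
  m2 <- train_trinet(gen$x, gen$y, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$branches$cnn$kernels, m2$branches$cnn$kernels)

  expect_error(train_trinet(gen$x, rep(0L, nrow(gen$x)), cfg),
               "all three classes")
})

test_that("fusion averages branch probabilities with a smallest-index tie rule", {
  bp <- rbind(c(0.6, 0.2, 0.2), c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2))
  expect_equal(colMeans(bp), c(0.5, 0.3, 0.2))   # hand average -> class 0

  gen <- toy_separable(n_per_class = 20, seed = 6)
  m <- train_trinet(gen$x, gen$y, trinet_config(epochs = 10, seed = 6))
  pr <- fuse_predict(m, gen$x)
  expect_true(all(abs(rowSums(pr$probs) - 1) < 1e-9))
  expect_true(all(pr$probs >= 0))
  expect_true(all(pr$class %in% 0:2))
  bp3 <- falldet:::trinet_branch_probs(m, gen$x)
  expect_equal(pr$probs, (bp3$lstm + bp3$cnn + bp3$rnn) / 3)

  # all branches identical => fused equals the branch output (idempotence)
  same <- (bp3$lstm + bp3$lstm + bp3$lstm) / 3
  expect_equal(same, bp3$lstm)
  # exact uniform tie resolves to class 0
  expect_equal(max.col(matrix(1 / 3, 1, 3), ties.method = "first"), 1L)

  expect_error(fuse_predict(list(), gen$x), "untrained")
})

test_that("more epochs do not hurt accuracy on the same seeded data", {
  gen <- toy_separable(n_per_class = 60, seed = 7)
  tr <- c(1:40, 61:100, 121:160)           # labels are blocked by class
  te <- setdiff(seq_len(180), tr)
  accs <- vapply(c(5, 60), function(ep) {
    m <- train_trinet(gen$x[tr, ], gen$y[tr], trinet_config(epochs = ep, seed = 7))
    mean(fuse_predict(m, gen$x[te, ])$class == gen$y[te])
  }, numeric(1))
  expect_gte(accs[2], accs[1] - 0.02)
})

test_that("HTLSS tuning of the CNN honours a collapsed box and never regresses", {
  gen <- toy_separable(n_per_class = 40, seed = 8)
  idx <- with(list(), {set.seed(8); sample(120)})
  tr <- idx[1:84]; va <- idx[85:120]
  point <- list(lo = c(8, 3, -1.3, 0.1), up = c(8, 3, -1.3, 0.1))
  cfg <- hsstl_config(dim = 4, pop_size = 4, max_iters = 2, seed = 8,
                      n_teachers = 2)
  res <- optimize_cnn(gen$x[tr, ], gen$y[tr], gen$x[va, ], gen$y[va],
                      config = cfg, space = point, short_epochs = 3,
                      final_epochs = 5)
  expect_equal(res$hyper$n_filters, 8L)
  expect_equal(res$hyper$kernel, 3L)
  expect_equal(res$hyper$lr, 10^-1.3)
  expect_equal(res$hyper$dropout, 0.1)
  expect_true(all(diff(res$result$history) <= 0))
})
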