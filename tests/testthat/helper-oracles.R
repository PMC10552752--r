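# Independent oracles used across the suite. Each is a deliberately naive
# re-implementation from first principles, kept free of any package internals
# so that agreement is evidence, not tautology.

# O(I^2) double-loop raw autocorrelation
autocorr_oracle <- function(a, m) {
  m <- abs(m)
  I <- length(a)
  s <- 0
  for (i in 0:(I - m - 1)) s <- s + a[i + m + 1] * a[i + 1]
  s
}

# one-vs-rest binary metrics straight from the printed definitions
metrics_oracle <- function(cm, c_idx) {
  tp <- cm[c_idx, c_idx]
  fp <- sum(cm[, c_idx]) - tp
  fn <- sum(cm[c_idx, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  div <- function(a, b) if (b == 0) 0 else a / b
  p <- div(tp, tp + fp)
  r <- div(tp, tp + fn)
  list(
    accuracy = div(tp + tn, tp + fp + fn + tn),
    precision = p,
    sensitivity = r,
    specificity = div(tn, tn + fp),
    f_measure = div(2 * p * r, p + r),
    mcc = div(tp * tn - fp * fn,
              sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn) * sqrt(tp + fp)),
    npv = div(tn, tn + fn),
    fpr = div(fp, fp + tn),
    fnr = div(fn, fn + tp)
  )
}

random_cm <- function(max_count = 30) {
  matrix(sample.int(max_count + 1, 9, replace = TRUE) - 1L, 3, 3)
}

# naive single LSTM step written directly from the gate recurrences
lstm_step_oracle <- function(x, h_prev, c_prev, p) {
  sig <- function(z) 1 / (1 + exp(-z))
  hx <- c(h_prev, x)
  i <- sig(as.vector(p$w_i %*% hx) + p$b_i)
  f <- sig(as.vector(p$w_f %*% hx) + p$b_f)
  g <- tanh(as.vector(p$w_C %*% hx) + p$b_c)
  c_new <- f * c_prev + i * g
  o <- sig(as.vector(p$w_o %*% hx) + p$b_o)
  list(h = o * tanh(c_new), c = c_new)
}

random_lstm_params <- function(H, in_dim) {
  rm_ <- function() matrix(rnorm(H * (H + in_dim)), H, H + in_dim)
  list(w_i = rm_(), w_f = rm_(), w_C = rm_(), w_o = rm_(),
       b_i = rnorm(H), b_f = rnorm(H), b_c = rnorm(H), b_o = rnorm(H))
}

# Canonical TLBO, coded standalone: greedy teacher phase toward the current
# best with the population mean, then the classical random-partner learner
# move. Shares the RNG stream convention of the package's degenerate mode:
# init is matrix(runif(n*d), n, d); per phase, members move in index order
# drawing (teacher) d uniforms, (learner) one partner then d uniforms.
tlbo_oracle <- function(objective, dim, lo, up, pop_size, max_iters, seed) {
  lo <- rep_len(lo, dim); up <- rep_len(up, dim)
  clamp <- function(x) pmin(pmax(x, lo), up)
  set.seed(seed)
  pos <- sweep(sweep(matrix(runif(pop_size * dim), pop_size, dim),
                     2, up - lo, "*"), 2, lo, "+")
  fit <- apply(pos, 1, objective)
  best <- min(fit)
  history <- numeric(0)
  for (t in seq_len(max_iters)) {
    for (i in seq_len(pop_size)) {
      q <- runif(dim)
      teacher <- pos[which.min(fit), ]
      m <- colMeans(pos)
      cand <- clamp(pos[i, ] + q * (teacher - 1 * m))
      f_new <- objective(cand)
      if (f_new < fit[i]) { pos[i, ] <- cand; fit[i] <- f_new }
    }
    for (i in seq_len(pop_size)) {
      j <- sample(setdiff(seq_len(pop_size), i), 1L)
      r <- runif(dim)
      step <- if (fit[i] < fit[j]) pos[i, ] - pos[j, ] else pos[j, ] - pos[i, ]
      cand <- clamp(pos[i, ] + r * step)
      f_new <- objective(cand)
      if (f_new < fit[i]) { pos[i, ] <- cand; fit[i] <- f_new }
    }
    best <- min(best, min(fit))
    history <- c(history, best)
  }
  list(best_fitness = best, history = history, positions = pos, fitness = fit)
}

sphere <- function(x) sum(x^2)

# small, separable PCA-free classification data for trinet tests
toy_separable <- function(n_per_class = 40, d = 6, separation = 2, seed = 1) {
  gen_feature_matrix(rep(n_per_class, 3), n_informative = d, n_noise = 0,
                     separation = separation, seed = seed)
}
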