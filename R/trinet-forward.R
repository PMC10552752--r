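# TriNet forward passes -------------------------------------------------------
#
# Reference (single-sample) forward passes for the three ensemble branches.
# The gated recurrences are implemented exactly as specified: the "RNN"
# branch uses the same LSTM-form gating as the LSTM branch (input, forget,
# output gates plus a tanh candidate), only with its own parameter set.
# Training uses the batched engine in trinet-train.R; these functions are the
# spec surface and the oracle targets.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM forward pass
#'
#' Runs the standard LSTM recurrences over a sequence:
#' `i_t = sigmoid(w_i [h, x] + b_i)`, `f_t = sigmoid(w_f [h, x] + b_f)`,
#' `c~ = tanh(w_C [h, x] + b_c)`, `c_t = f_t * c_{t-1} + i_t * c~`,
#' `O_t = sigmoid(w_o [h, x] + b_o)`, `h_t = O_t * tanh(c_t)`
#' (elementwise products; `[h, x]` is the concatenation of the previous
#' hidden state and the current input).
#'
#' @param seq Input sequence: numeric vector (scalar inputs) or
#'   `t x input_dim` matrix.
#' @param params List with weight matrices `w_i`, `w_f`, `w_C`, `w_o`
#'   (each `hidden x (hidden + input_dim)`) and biases `b_i`, `b_f`, `b_c`,
#'   `b_o` (length `hidden`).
#' @param h0,c0 Initial hidden and cell state (default zeros).
#' @return List with `h` and `c`, both `t x hidden` matrices.
#' @export
lstm_forward <- function(seq, params, h0 = NULL, c0 = NULL) {
  x <- if (is.matrix(seq)) seq else matrix(seq, ncol = 1)
  H <- nrow(params$w_i)
  in_dim <- ncol(params$w_i) - H
  if (ncol(x) != in_dim) {
    stopf("lstm_forward(): input dim %d but weights expect %d", ncol(x), in_dim)
  }
  for (w in c("w_f", "w_C", "w_o")) {
    if (!all(dim(params[[w]]) == c(H, H + in_dim))) {
      stopf("lstm_forward(): %s has inconsistent shape", w)
    }
  }
  h <- if (is.null(h0)) rep(0, H) else h0
  c_state <- if (is.null(c0)) rep(0, H) else c0
  TT <- nrow(x)
  hs <- matrix(0, TT, H)
  cs <- matrix(0, TT, H)
  for (t in seq_len(TT)) {
    hx <- c(h, x[t, ])
    i_g <- sigmoid(drop(params$w_i %*% hx) + params$b_i)
    f_g <- sigmoid(drop(params$w_f %*% hx) + params$b_f)
    g <- tanh(drop(params$w_C %*% hx) + params$b_c)
    c_state <- f_g * c_state + i_g * g
    o_g <- sigmoid(drop(params$w_o %*% hx) + params$b_o)
    h <- o_g * tanh(c_state)
    hs[t, ] <- h
    cs[t, ] <- c_state
  }
  list(h = hs, c = cs)
}

#' Gated RNN forward pass
#'
#' The gated recurrent branch uses LSTM-form recurrences with its own
#' parameter naming: input gate `ie_t`, forget gate `fo_t`, output gate
#' `og_t`, candidate `i~_t = tanh(u_i [a, x] + b_i)`, cell state
#' `i_t = fo_t * i_{t-1} + ie_t * i~_t`, hidden `h_t = og_t * tanh(i_t)`.
#' With parameters mapped one-to-one it is numerically identical to
#' [lstm_forward()].
#'
#' @param seq Input sequence as in [lstm_forward()].
#' @param params List with weights `u_ie`, `u_fo`, `u_og`, `u_i` and biases
#'   `b_ie`, `b_fo`, `b_og`, `b_i`.
#' @param a0,i0 Initial hidden and cell state (default zeros).
#' @return List with `h` (hidden sequence) and `cell` (cell-state sequence).
#' @export
rnn_forward <- function(seq, params, a0 = NULL, i0 = NULL) {
  out <- lstm_forward(seq, params = list(
    w_i = params$u_ie, b_i = params$b_ie,
    w_f = params$u_fo, b_f = params$b_fo,
    w_C = params$u_i, b_c = params$b_i,
    w_o = params$u_og, b_o = params$b_og
  ), h0 = a0, c0 = i0)
  list(h = out$h, cell = out$c)
}

#' 1-D valid convolution
#'
#' Sliding dot product of `kernel` over `x` after zero-padding `padding`
#' samples on each side; output length `length(x) + 2*padding - k + 1`.
#'
#' @param x Numeric signal.
#' @param kernel Numeric kernel (length at most the padded signal).
#' @param padding Zero-padding per side (default 0).
#' @return Numeric vector of convolution outputs.
#' @export
conv1d <- function(x, kernel, padding = 0) {
  if (padding > 0) x <- c(rep(0, padding), x, rep(0, padding))
  k <- length(kernel)
  n <- length(x)
  if (n < k) stopf("conv1d(): input shorter than kernel")
  L <- n - k + 1L
  vapply(seq_len(L), function(j) sum(x[j:(j + k - 1L)] * kernel), numeric(1))
}

#' 2-D valid convolution
#'
#' The image-form convolution
#' `f(j, g) = sum_i sum_l k(i, l) * m(j + i, g + l)` over zero-based kernel
#' offsets; kept as a utility for fidelity checks of the 1-D specialization
#' used by the CNN branch.
#'
#' @param m Numeric matrix (image).
#' @param kernel Numeric matrix (square or rectangular kernel).
#' @return Matrix of valid convolution outputs.
#' @export
conv2d <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  oh <- nrow(m) - kh + 1L
  ow <- ncol(m) - kw + 1L
  if (oh < 1 || ow < 1) stopf("conv2d(): kernel larger than input")
  out <- matrix(0, oh, ow)
  for (j in seq_len(oh)) {
    for (g in seq_len(ow)) {
      out[j, g] <- sum(kernel * m[j:(j + kh - 1L), g:(g + kw - 1L)])
    }
  }
  out
}

#' Rectified linear unit
#'
#' `relu(f) = f` for `f > 0`, else 0.
#'
#' @param x Numeric input.
#' @return Elementwise max(x, 0).
#' @export
relu <- function(x) pmax(x, 0)

#' 1-D max pooling
#'
#' Window maxima with the floor output-length rule:
#' `floor((length(x) - pool) / stride) + 1` windows.
#'
#' @param x Numeric signal.
#' @param pool Window size.
#' @param stride Step between windows (default `pool`).
#' @return Numeric vector of window maxima.
#' @export
maxpool1d <- function(x, pool, stride = pool) {
  n <- length(x)
  if (n < pool) stopf("maxpool1d(): input shorter than pool window")
  L <- (n - pool) %/% stride + 1L
  vapply(seq_len(L), function(w) {
    s <- (w - 1L) * stride + 1L
    max(x[s:(s + pool - 1L)])
  }, numeric(1))
}

softmax <- function(z) {
  if (is.matrix(z)) {
    e <- exp(z - apply(z, 1, max))
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' 1-D CNN branch forward pass
#'
#' Valid 1-D convolution of each filter over the input signal (with optional
#' zero padding), ReLU activation, max pooling with the floor-rule output
#' length, then a dense softmax head over the 3 fall classes.
#'
#' @param x Numeric input signal (the feature vector treated as a 1-D
#'   signal), at least as long as the kernel.
#' @param params List with `kernels` (`k x n_filters` matrix), `bias`
#'   (length `n_filters`), `padding`, `pool`, `stride`, `w_out`
#'   (`(pooled_len * n_filters) x 3`), `b_out` (length 3).
#' @return Probability vector over classes 0:2 (sums to 1).
#' @export
cnn_forward <- function(x, params) {
  k <- nrow(params$kernels)
  nf <- ncol(params$kernels)
  if (length(x) + 2 * params$padding < k) {
    stopf("cnn_forward(): input shorter than kernel")
  }
  pooled <- unlist(lapply(seq_len(nf), function(f) {
    z <- conv1d(x, params$kernels[, f], padding = params$padding) +
      params$bias[f]
    maxpool1d(relu(z), params$pool, params$stride)
  }))
  softmax(drop(pooled %*% params$w_out) + params$b_out)
}
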