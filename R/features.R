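# Feature extraction ----------------------------------------------------------
#
# Three extractors feed the selection stage: seven per-channel statistical
# moments, raw lagged autocorrelation of each channel signal, and PCA on the
# standardized design matrix with eigenvalue thresholding. Moment
# conventions follow the pipeline's definitions exactly: population
# denominators, Pearson's second skewness coefficient 3*(mean - median)/sd,
# and non-excess kurtosis m4 / m2^2.

#' Statistical moment features of a sensor window
#'
#' Per channel, emits `[mean, std, variance, min, max, skewness, kurtosis]`
#' in that order. Standard deviation and variance use the population
#' denominator `N`; skewness is Pearson's second coefficient
#' `3 * (mean - median) / std`; kurtosis is the non-excess ratio
#' `m4 / m2^2`. For a constant channel (`std = 0`) skewness and kurtosis are
#' defined as 0.
#'
#' @param window A `sensor_window` (see [gen_sensor_windows()]) or a numeric
#'   matrix (rows = samples, columns = channels) with at least 2 rows.
#' @return Named numeric vector of length `7 * n_channels`; names are
#'   `<channel>_<stat>`.
#' @export
stat_features <- function(window) {
  m <- if (inherits(window, "sensor_window")) window$samples else as.matrix(window)
  if (nrow(m) < 2L) stopf("stat_features(): need at least 2 samples")
  ch_names <- if (inherits(window, "sensor_window")) window$channel_names else
    colnames(m) %||% paste0("ch", seq_len(ncol(m)))
  stats_one <- function(x) {
    if (length(x) == 0 || anyNA(x)) stopf("stat_features(): empty or NA channel")
    n <- length(x)
    mu <- mean(x)
    v <- sum((x - mu)^2) / n            # population variance
    s <- sqrt(v)
    if (s == 0) {
      skew <- 0
      kurt <- 0
    } else {
      skew <- 3 * (mu - median(x)) / s
      m2 <- v
      m4 <- sum((x - mu)^4) / n
      kurt <- m4 / m2^2
    }
    c(mean = mu, std = s, variance = v, min = min(x), max = max(x),
      skewness = skew, kurtosis = kurt)
  }
  out <- lapply(seq_len(ncol(m)), function(j) stats_one(m[, j]))
  names(out) <- ch_names
  vec <- unlist(out)
  names(vec) <- as.vector(t(outer(ch_names, names(out[[1]]), paste, sep = "_")))
  vec
}

#' Raw lagged autocorrelation of a signal
#'
#' Computes the raw (non-mean-subtracted) autocorrelation sequence
#' `s(m) = sum_{i=0}^{I-m-1} a(i+m) * a(i)` for the requested non-negative
#' lags, extended symmetrically for negative lags. With `normalize = TRUE`
#' (the default) returns `r(m) = s(m) / s(0)`; an all-zero signal
#' (`s(0) = 0`) yields `r(m) = 0` for all lags.
#'
#' @param signal Numeric vector of length `I`.
#' @param lags Integer lags, each with `|lag| < I`. Default `1:10`.
#' @param normalize Divide by `s(0)`.
#' @return Named numeric vector, one value per requested lag
#'   (names `lag<k>`).
#' @export
autocorr <- function(signal, lags = 1:10, normalize = TRUE) {
  a <- as.numeric(signal)
  I <- length(a)
  if (any(abs(lags) >= I)) stopf("autocorr(): |lag| must be < signal length")
  s_raw <- function(m) {
    m <- abs(m)
    if (m == 0) sum(a * a) else sum(a[(1 + m):I] * a[seq_len(I - m)])
  }
  s0 <- s_raw(0)
  vals <- vapply(lags, s_raw, numeric(1))
  if (normalize) {
    vals <- if (s0 == 0) rep(0, length(vals)) else vals / s0
  }
  stats::setNames(vals, paste0("lag", lags))
}

#' Feature matrix from a collection of sensor windows
#'
#' Concatenates, per window, the per-channel moment features
#' ([stat_features()]) followed by the per-channel normalized
#' autocorrelations at lags `1..n_lags` ([autocorr()]).
#'
#' @param windows List of `sensor_window` objects.
#' @param n_lags Autocorrelation lags per channel (default 10).
#' @return List with `x` (numeric matrix, one row per window, named columns)
#'   and `y` (integer labels).
#' @export
build_feature_matrix <- function(windows, n_lags = 10L) {
  stopifnot(length(windows) > 0)
  rows <- lapply(windows, function(w) {
    mo <- stat_features(w)
    ac <- unlist(lapply(seq_along(w$channel_names), function(j) {
      stats::setNames(autocorr(w$samples[, j], lags = seq_len(n_lags)),
                      paste0(w$channel_names[j], "_lag", seq_len(n_lags)))
    }))
    c(mo, ac)
  })
  x <- do.call(rbind, rows)
  y <- vapply(windows, function(w) as.integer(w$label), integer(1))
  list(x = x, y = y)
}

#' Fit a PCA model with eigenvalue thresholding
#'
#' Standardizes each column (z-score `(x - mu) / sigma` by default; true
#' min-max scaling available via `scale_method = "minmax"`), forms the
#' covariance matrix with the `N - 1` denominator, and eigendecomposes it.
#' Eigenvalues are sorted descending. Components are retained either as the
#' smallest `k` whose cumulative variance reaches `variance_fraction`, or —
#' when an absolute `lambda_eig` threshold is supplied — as all components
#' with eigenvalue `>= lambda_eig` (noise eigenvalues below the threshold are
#' discarded). At least one component is always retained. An optional
#' eigenvector-norm threshold `v_vec` is accepted for completeness but is off
#' by default (thresholding unit-norm eigenvectors is a no-op for
#' `v_vec <= 1`).
#'
#' @param x Numeric matrix or data frame, rows = observations (at least 2).
#' @param variance_fraction Cumulative-variance retention target in (0, 1].
#' @param lambda_eig Optional absolute eigenvalue threshold; overrides
#'   `variance_fraction` when given.
#' @param v_vec Optional eigenvector-norm threshold (rarely useful; columns
#'   with norm below it are zeroed).
#' @param scale_method `"zscore"` (default) or `"minmax"`.
#' @return A `pca_model`: list with `mu`, `sigma` (scale offsets/divisors),
#'   `eigenvalues` (descending), `eigenvectors` (orthonormal columns),
#'   `retained_k`, plus the thresholds used.
#' @export
pca_fit <- function(x, variance_fraction = 0.95, lambda_eig = NULL,
                    v_vec = NULL, scale_method = c("zscore", "minmax")) {
  scale_method <- match.arg(scale_method)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("pca_fit(): need at least 2 rows")
  if (scale_method == "zscore") {
    mu <- colMeans(x)
    sigma <- apply(x, 2, sd)
  } else {
    mu <- apply(x, 2, min)
    sigma <- apply(x, 2, max) - mu
  }
  if (any(sigma == 0)) {
    warning("pca_fit(): zero-variance column(s); scale set to 1", call. = FALSE)
    sigma[sigma == 0] <- 1
  }
  xs <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  C <- stats::cov(xs)                      # N - 1 denominator
  eig <- eigen(C, symmetric = TRUE)        # eigenvalues descending
  lambda <- eig$values
  V <- eig$vectors
  if (!is.null(v_vec)) {
    norms <- sqrt(colSums(V^2))
    V[, norms < v_vec] <- 0
  }
  if (!is.null(lambda_eig)) {
    k <- sum(lambda >= lambda_eig)
  } else {
    cumfrac <- cumsum(pmax(lambda, 0)) / sum(pmax(lambda, 0))
    k <- which(cumfrac >= variance_fraction)[1]
    if (is.na(k)) k <- length(lambda)
  }
  k <- max(1L, as.integer(k))
  structure(
    list(mu = mu, sigma = sigma, eigenvalues = lambda, eigenvectors = V,
         lambda_eig = lambda_eig, v_vec = v_vec, retained_k = k,
         scale_method = scale_method,
         feature_names = colnames(x) %||% paste0("f", seq_len(ncol(x)))),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d features -> %d components (%s scaling)\n",
              length(x$mu), x$retained_k, x$scale_method))
  cat("eigenvalues:", paste(signif(head(x$eigenvalues, 8), 4), collapse = " "),
      if (length(x$eigenvalues) > 8) "..." else "", "\n")
  invisible(x)
}

#' Project data onto the retained principal components
#'
#' Applies the model's standardization then multiplies by the retained
#' eigenvector columns, giving the transformed feature matrix.
#'
#' @param x Matrix with the same columns the model was fitted on.
#' @param model A [pca_fit()] model.
#' @return Matrix of shape `nrow(x) x retained_k` (columns `PC1..`).
#' @export
pca_transform <- function(x, model) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$mu)) {
    stopf("pca_transform(): %d columns but model expects %d",
          ncol(x), length(model$mu))
  }
  xs <- sweep(sweep(x, 2, model$mu), 2, model$sigma, "/")
  scores <- xs %*% model$eigenvectors[, seq_len(model$retained_k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(model$retained_k))
  scores
}
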