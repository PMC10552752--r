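# Synthetic cStick-style data -------------------------------------------------
#
# The generator emulates the schema of the Elderly Fall Prediction and
# Detection dataset as recorded by the cStick wearable: six sensor channels
# (distance, pressure level, heart-rate variability, blood sugar, SpO2,
# accelerometer magnitude) plus a 3-class decision label
# (0 = no fall, 1 = slip/stumble/predicted fall, 2 = actual fall).
# Continuous channels are class-conditional Gaussians whose means are shifted
# by `separation` pooled standard deviations between adjacent classes, then
# clamped to physical ranges; the ordinal pressure level comes from a
# thresholded latent Gaussian.

#' cStick schema column names
#'
#' `CSTICK_FEATURES` are the six sensor channels; `CSTICK_COLUMNS` appends
#' the `decision` label, giving the canonical CSV column order.
#'
#' @format Character vectors.
#' @export
CSTICK_FEATURES <- c("distance", "pressure", "hrv", "sugar", "spo2", "accel")

#' @rdname CSTICK_FEATURES
#' @export
CSTICK_COLUMNS <- c(CSTICK_FEATURES, "decision")

# Per-channel base mean, within-class sd, direction of the class shift and
# physical clamping range. Units: distance cm, hrv beats/min, sugar mg/dL,
# spo2 %, accel g. The source dataset documents no units or ranges for
# distance, sugar or accelerometer; these defaults are plausible clinical
# values, documented rather than inferred.
cstick_channel_spec <- function() {
  data.frame(
    channel = c("distance", "hrv", "sugar", "spo2", "accel"),
    base    = c(20,  72, 110, 96.5, 0.4),
    sd      = c(10,  9,  22,  1.4,  0.25),
    dir     = c(1,   1,  1,  -1,    1),
    lo      = c(0,   20, 40,  70,   0),
    hi      = c(Inf, 220, 500, 100, Inf),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cStick sensor table
#'
#' Draws a labeled table of wearable-sensor records with exact per-class
#' counts. Continuous channels are class-conditional Gaussians: the mean of
#' class `c` is shifted by `c * separation` within-class standard deviations
#' from the class-0 mean (direction depends on the channel; SpO2 falls while
#' the others rise), then clamped to the channel's physical range. The ordinal
#' pressure level in \{0,1,2\} is obtained by thresholding a latent Gaussian
#' whose mean shifts with the class by the same `separation`.
#'
#' With `separation = 0` all classes share one distribution, so the label
#' carries no signal; the default 2.0 pooled-sigma separation produces the
#' strongly separable regime in which high-accuracy classifiers are expected.
#'
#' @param n_per_class Integer vector of length 3 (counts for classes 0, 1, 2),
#'   optionally named `"0"`, `"1"`, `"2"`.
#' @param separation Class-mean shift between adjacent classes, in pooled
#'   standard-deviation units. Non-negative.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   table bit-exactly.
#' @return A `cstick_table`: a `data.frame` with columns
#'   `distance, pressure, hrv, sugar, spo2, accel, decision`, class counts as
#'   requested, rows grouped by class (0 first).
#' @examples
#' tab <- gen_cstick_table(c(10, 10, 10), separation = 2, seed = 1)
#' table(tab$decision)
#' @export
gen_cstick_table <- function(n_per_class = c(`0` = 690, `1` = 682, `2` = 667),
                             separation = 2.0, seed = 1L) {
  if (length(n_per_class) != 3L) {
    stopf("`n_per_class` must have length 3 (classes 0, 1, 2)")
  }
  if (!is.null(names(n_per_class))) {
    if (!setequal(names(n_per_class), c("0", "1", "2"))) {
      stopf("unknown class key in `n_per_class`: %s",
            paste(setdiff(names(n_per_class), c("0", "1", "2")), collapse = ", "))
    }
    n_per_class <- n_per_class[c("0", "1", "2")]
  }
  n_per_class <- as.integer(n_per_class)
  if (anyNA(n_per_class) || any(n_per_class < 0)) {
    stopf("`n_per_class` must be non-negative integers")
  }
  if (!is.numeric(separation) || length(separation) != 1L || separation < 0) {
    stopf("`separation` must be a single non-negative number")
  }

  spec <- cstick_channel_spec()
  with_seed(seed, {
    blocks <- lapply(0:2, function(cls) {
      n <- n_per_class[cls + 1L]
      out <- data.frame(matrix(numeric(0), nrow = n, ncol = 0))
      for (j in seq_len(nrow(spec))) {
        ch <- spec[j, ]
        mu <- ch$base + ch$dir * cls * separation * ch$sd
        x <- rnorm(n, mean = mu, sd = ch$sd)
        out[[ch$channel]] <- pmin(pmax(x, ch$lo), ch$hi)
      }
      # latent-Gaussian ordinal pressure: cutpoints sit at the tercile points
      # of the class-0 latent plus the midpoints between adjacent class means
      z <- rnorm(n, mean = cls * separation, sd = 1)
      t1 <- 0.5 * separation + qnorm(1 / 3)
      t2 <- 1.5 * separation + qnorm(2 / 3)
      out$pressure <- as.integer(findInterval(z, c(t1, t2)))
      out$decision <- rep(cls, n)
      out[, CSTICK_COLUMNS]
    })
    tab <- do.call(rbind, blocks)
    rownames(tab) <- NULL
    as_cstick_table(tab, seed = seed)
  })
}

as_cstick_table <- function(df, seed = NULL) {
  stopifnot(is.data.frame(df))
  class(df) <- c("cstick_table", "data.frame")
  attr(df, "seed") <- seed
  df
}

#' @export
print.cstick_table <- function(x, ...) {
  cat(sprintf("<cstick_table> %d records\n", nrow(x)))
  if (nrow(x) > 0) {
    counts <- table(factor(x$decision, levels = 0:2))
    cat(sprintf("classes: no-fall %d | slip/predicted %d | fall %d\n",
                counts[["0"]], counts[["1"]], counts[["2"]]))
  }
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' Generate per-record sensor windows
#'
#' Expands each table record into a fixed-length multichannel time series
#' emulating one monitoring episode. Class 0 episodes are stationary
#' low-variance noise around the record's channel values; class 1 adds a
#' transient mid-window accelerometer spike; class 2 adds a larger spike
#' followed by a sustained level shift on the accelerometer channel (the
#' impact-then-lying-still signature of a real fall).
#'
#' @param table A [gen_cstick_table()] table.
#' @param window_len Samples per window, at least 8.
#' @param rate Sampling frequency in Hz (metadata only).
#' @param seed Integer seed.
#' @return List of `sensor_window` objects; each has `samples`
#'   (`window_len` x 6 matrix), `rate`, `label`, `channel_names`.
#' @export
gen_sensor_windows <- function(table, window_len = 128L, rate = 50, seed = 1L) {
  if (window_len < 8L) stopf("`window_len` must be at least 8")
  feats <- as.matrix(as.data.frame(table)[, CSTICK_FEATURES])
  spec <- cstick_channel_spec()
  noise_sd <- stats::setNames(rep(0.05, 6), CSTICK_FEATURES)
  noise_sd[spec$channel] <- 0.05 * spec$sd
  accel_col <- match("accel", CSTICK_FEATURES)
  t_idx <- seq_len(window_len)
  mid <- window_len / 2
  with_seed(seed, {
    lapply(seq_len(nrow(feats)), function(i) {
      base <- matrix(rep(feats[i, ], each = window_len), nrow = window_len)
      noise <- matrix(rnorm(window_len * 6), nrow = window_len) *
        rep(noise_sd, each = window_len)
      samples <- base + noise
      cls <- table$decision[i]
      if (cls >= 1) {
        amp <- if (cls == 2) 3.0 else 1.2      # spike amplitude, g
        width <- max(2, window_len / 16)
        spike <- amp * exp(-((t_idx - mid)^2) / (2 * width^2))
        samples[, accel_col] <- samples[, accel_col] + spike
        if (cls == 2) {                        # sustained post-impact shift
          samples[t_idx > mid, accel_col] <-
            samples[t_idx > mid, accel_col] + 1.0
        }
      }
      structure(
        list(samples = samples, rate = rate, label = cls,
             channel_names = CSTICK_FEATURES),
        class = "sensor_window"
      )
    })
  })
}

#' @export
print.sensor_window <- function(x, ...) {
  cat(sprintf("<sensor_window> %d samples x %d channels @ %g Hz, label %d\n",
              nrow(x$samples), ncol(x$samples), x$rate, x$label))
  invisible(x)
}

#' Inject missing values into a sensor table
#'
#' Independently replaces each non-label cell by `NA` with probability
#' `rate`. The decision label is never altered. Used to exercise the
#' missing-value cleaning stage.
#'
#' @param table A `cstick_table`.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The table with missing cells.
#' @export
inject_missing <- function(table, rate, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    stopf("`rate` must be a single number in [0, 1)")
  }
  if (rate == 0) return(table)
  with_seed(seed, {
    for (col in CSTICK_FEATURES) {
      hit <- runif(nrow(table)) < rate
      table[[col]][hit] <- NA
    }
    table
  })
}

#' Read / write cStick tables as CSV
#'
#' RFC-4180 CSV with header `distance,pressure,hrv,sugar,spo2,accel,decision`;
#' missing cells are serialized as empty fields.
#'
#' @param table A `cstick_table`.
#' @param path File path.
#' @return `write_cstick()` returns `path` invisibly; `read_cstick()` returns
#'   a `cstick_table`.
#' @export
write_cstick <- function(table, path) {
  write.csv(as.data.frame(table)[, CSTICK_COLUMNS], path,
            row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cstick
#' @export
read_cstick <- function(path) {
  df <- read.csv(path, na.strings = "", colClasses = "numeric")
  missing_cols <- setdiff(CSTICK_COLUMNS, names(df))
  if (length(missing_cols)) {
    stopf("CSV lacks required columns: %s", paste(missing_cols, collapse = ", "))
  }
  df$pressure <- as.integer(df$pressure)
  df$decision <- as.integer(df$decision)
  as_cstick_table(df[, CSTICK_COLUMNS])
}

#' Generate a labeled feature matrix with planted informative columns
#'
#' Builds a design matrix in which the first `n_informative` columns carry
#' class signal (adjacent class means `separation` standard deviations apart,
#' unit within-class variance) and the remaining `n_noise` columns are pure
#' standard-normal noise. Ground truth for feature-selection experiments.
#'
#' @param n_per_class Length-3 integer vector of per-class counts.
#' @param n_informative,n_noise Column counts.
#' @param separation Adjacent-class mean shift in sd units.
#' @param seed Integer seed.
#' @return List with `x` (matrix, named columns `inf1..`, `noise1..`),
#'   `y` (integer labels 0:2), `informative` (column indices of the signal).
#' @export
gen_feature_matrix <- function(n_per_class = c(200, 200, 200),
                               n_informative = 5, n_noise = 15,
                               separation = 2.0, seed = 1L) {
  stopifnot(length(n_per_class) == 3L, n_informative >= 1, n_noise >= 0)
  y <- rep(0:2, times = n_per_class)
  n <- length(y)
  with_seed(seed, {
    signal <- matrix(rnorm(n * n_informative), n, n_informative) +
      outer(y * separation, rep(1, n_informative))
    noise <- if (n_noise > 0) matrix(rnorm(n * n_noise), n, n_noise) else
      matrix(numeric(0), n, 0)
    x <- cbind(signal, noise)
    colnames(x) <- c(
      paste0("inf", seq_len(n_informative)),
      if (n_noise > 0) paste0("noise", seq_len(n_noise))
    )
    list(x = x, y = y, informative = seq_len(n_informative))
  })
}
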