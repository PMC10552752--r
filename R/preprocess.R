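# Cleaning and splitting ------------------------------------------------------

#' Validate a cStick table against the sensor schema
#'
#' Report-only check of column presence, types, physical ranges (SpO2 in
#' [70, 100], pressure in \{0,1,2\}) and the label domain \{0,1,2\}. Never
#' mutates its input. Missing cells are not violations (they are handled by
#' the cleaning stage).
#'
#' @param table A data frame in the cStick schema.
#' @return A data.frame of violations with columns `row`, `column`, `problem`;
#'   zero rows for a clean table.
#' @export
validate_schema <- function(table) {
  df <- as.data.frame(table)
  viol <- list()
  note <- function(row, column, problem) {
    viol[[length(viol) + 1L]] <<- data.frame(
      row = row, column = column, problem = problem, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(CSTICK_COLUMNS, names(df))
  for (col in missing_cols) note(NA_integer_, col, "column absent")
  check_range <- function(col, lo, hi, what) {
    if (!col %in% names(df)) return()
    bad <- which(!is.na(df[[col]]) & (df[[col]] < lo | df[[col]] > hi))
    for (r in bad) note(r, col, what)
  }
  check_range("spo2", 70, 100, "spo2 outside [70, 100]")
  for (col in c("distance", "hrv", "sugar", "accel")) {
    check_range(col, 0, Inf, sprintf("%s negative", col))
  }
  if ("pressure" %in% names(df)) {
    bad <- which(!is.na(df$pressure) & !df$pressure %in% 0:2)
    for (r in bad) note(r, "pressure", "pressure level not in {0,1,2}")
  }
  if ("decision" %in% names(df)) {
    bad <- which(!is.na(df$decision) & !df$decision %in% 0:2)
    for (r in bad) note(r, "decision", "decision label not in {0,1,2}")
  }
  if (length(viol) == 0) {
    data.frame(row = integer(0), column = character(0),
               problem = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, viol)
  }
}

#' Remove rows containing missing values
#'
#' Keeps exactly the rows with no missing cell in any sensor column,
#' preserving the original order. Idempotent.
#'
#' @param table A `cstick_table` (or data frame in the schema).
#' @return The filtered table; warns (without erroring) if nothing survives.
#' @export
drop_missing <- function(table) {
  df <- as.data.frame(table)
  keep <- stats::complete.cases(df[, intersect(CSTICK_FEATURES, names(df))])
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0 && nrow(df) > 0) {
    warning("drop_missing(): all rows removed", call. = FALSE)
  }
  as_cstick_table(out, seed = attr(table, "seed"))
}

#' Resolve missing cells by an imputation policy
#'
#' @param table A `cstick_table`.
#' @param policy One of `"drop"` (delegate to [drop_missing()]),
#'   `"column-mean"` (replace by the column mean over observed values), or
#'   `"forward-fill"` (copy the last observed value in row order; a leading
#'   missing run falls back to the column mean).
#' @return A table with no missing sensor cells.
#' @export
impute_nulls <- function(table, policy = c("drop", "column-mean", "forward-fill")) {
  policy <- match.arg(policy)
  if (policy == "drop") return(drop_missing(table))
  df <- as.data.frame(table)
  for (col in intersect(CSTICK_FEATURES, names(df))) {
    x <- df[[col]]
    if (!anyNA(x)) next
    if (all(is.na(x))) {
      stopf("impute_nulls(): column '%s' is entirely missing", col)
    }
    mu <- mean(x, na.rm = TRUE)
    if (policy == "column-mean") {
      x[is.na(x)] <- mu
    } else {                       # forward-fill
      for (i in seq_along(x)) {
        if (is.na(x[i])) x[i] <- if (i == 1L) mu else x[i - 1L]
      }
      # leading NA run after the first element still empty? (x[1] was set)
    }
    if (col == "pressure") x <- as.integer(round(x))
    df[[col]] <- x
  }
  as_cstick_table(df, seed = attr(table, "seed"))
}

#' Split a table into training and testing sets
#'
#' The train fraction follows the dataset's "learning rate" convention:
#' `|train| = floor(learning_rate * n)`, the remainder is the test set. The
#' default split is a seeded shuffle; with `stratified = TRUE` the train
#' quota is apportioned across classes by largest remainder, so per-class
#' train proportions differ from the global proportion by less than one row.
#'
#' @param table A non-empty `cstick_table`.
#' @param learning_rate Train fraction in (0, 1); e.g. 0.70 on 2,039 records
#'   gives 1,427 train / 612 test rows and 0.80 gives 1,631 / 408.
#' @param stratified Apportion per class rather than globally.
#' @param seed Integer seed for the shuffle.
#' @return List with elements `train` and `test` (both `cstick_table`s,
#'   disjoint, union equal to the input).
#' @export
split_dataset <- function(table, learning_rate = 0.7, stratified = FALSE,
                          seed = 1L) {
  df <- as.data.frame(table)
  n <- nrow(df)
  if (n == 0) stopf("split_dataset(): table is empty")
  if (!is.numeric(learning_rate) || learning_rate <= 0 || learning_rate >= 1) {
    stopf("`learning_rate` must be in (0, 1)")
  }
  n_train <- floor(learning_rate * n)
  if (n_train == 0 || n_train == n) {
    stopf("degenerate split: learning_rate %.3f on %d rows yields an empty set",
          learning_rate, n)
  }
  idx_train <- with_seed(seed, {
    if (!stratified) {
      sample.int(n)[seq_len(n_train)]
    } else {
      cls_idx <- split(seq_len(n), factor(df$decision, levels = 0:2))
      quota <- vapply(cls_idx, length, 1L) * learning_rate
      base <- floor(quota)
      extra <- n_train - sum(base)
      if (extra > 0) {
        give <- order(quota - base, decreasing = TRUE)[seq_len(extra)]
        base[give] <- base[give] + 1L
      }
      unlist(lapply(seq_along(cls_idx), function(k) {
        ids <- cls_idx[[k]]
        if (length(ids) == 0) return(integer(0))
        sample(ids)[seq_len(base[k])]
      }), use.names = FALSE)
    }
  })
  train <- df[sort(idx_train), , drop = FALSE]
  test <- df[setdiff(seq_len(n), idx_train), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = as_cstick_table(train), test = as_cstick_table(test))
}
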