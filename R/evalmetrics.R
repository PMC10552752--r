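# Confusion-matrix metric suite and ROC ---------------------------------------

#' Confusion matrix for the 3-class fall problem
#'
#' `counts[i, j]` is the number of samples with true class `i - 1` predicted
#' as class `j - 1` (labels 0:2; rows = truth, columns = prediction).
#'
#' @param y_true,y_pred Equal-length integer vectors with labels in 0:2.
#' @param n_classes Number of classes (default 3).
#' @return A `confusion_matrix` (integer matrix with class labels as
#'   dimnames).
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 3L) {
  if (length(y_true) != length(y_pred)) {
    stopf("confusion_matrix(): length mismatch (%d vs %d)",
          length(y_true), length(y_pred))
  }
  labs <- 0:(n_classes - 1L)
  if (!all(y_true %in% labs) || !all(y_pred %in% labs)) {
    stopf("confusion_matrix(): labels must be in {%s}",
          paste(labs, collapse = ","))
  }
  cm <- table(factor(y_true, levels = labs), factor(y_pred, levels = labs))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = labs, pred = labs))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

# 0/0 -> 0 with a warning-free default (degenerate folds must not crash)
safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

metrics_from_counts <- function(tp, fp, fn, tn) {
  # doubles: the MCC denominator overflows integer range at modest n
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  prec <- safe_div(tp, tp + fp)
  sens <- safe_div(tp, tp + fn)
  list(
    accuracy = safe_div(tp + tn, tp + fp + fn + tn),
    precision = prec,
    sensitivity = sens,
    specificity = safe_div(tn, tn + fp),
    f_measure = safe_div(2 * prec * sens, prec + sens),
    mcc = safe_div(tp * tn - fp * fn,
                   sqrt((tp + fn) * (tn + fp) * (tn + fn) * (tp + fp))),
    npv = safe_div(tn, tn + fn),
    fpr = safe_div(fp, fp + tn),
    fnr = safe_div(fn, fn + tp)
  )
}

#' Nine-metric report from a confusion matrix
#'
#' Reduces the multiclass matrix one-vs-rest per class and computes accuracy,
#' precision, sensitivity (recall), specificity, F-measure, MCC, NPV, FPR and
#' FNR from the binary counts. `"macro"` averages the per-class values,
#' `"per-class"` returns one row per class, `"binary"` treats class `positive`
#' against the rest. In the binary reduction `fpr = 1 - specificity` and
#' `fnr = 1 - sensitivity` hold exactly. Any 0/0 cell is defined as 0.
#'
#' The F-measure is the standard `F1 = 2PR/(P+R)`; `f_variant = "product"`
#' gives the plain ratio `PR/(P+R)` for comparison with reports that use it.
#'
#' @param cm A [confusion_matrix()] (or any square count matrix).
#' @param mode `"macro"`, `"per-class"` or `"binary"`.
#' @param positive Positive class label for `mode = "binary"` (default 2,
#'   the actual-fall class).
#' @param f_variant `"standard"` or `"product"`.
#' @return For `"macro"`/`"binary"`: a `metrics_report` (named list of the 9
#'   metrics plus `mode`). For `"per-class"`: a data.frame, one row per
#'   class.
#' @export
metrics_report <- function(cm, mode = c("macro", "per-class", "binary"),
                           positive = 2L,
                           f_variant = c("standard", "product")) {
  mode <- match.arg(mode)
  f_variant <- match.arg(f_variant)
  cm <- unclass(cm)
  if (sum(cm) == 0) stopf("metrics_report(): empty confusion matrix")
  n_classes <- nrow(cm)
  ovr <- function(c_idx) {
    tp <- cm[c_idx, c_idx]
    fp <- sum(cm[-c_idx, c_idx])
    fn <- sum(cm[c_idx, -c_idx])
    tn <- sum(cm[-c_idx, -c_idx])
    m <- metrics_from_counts(tp, fp, fn, tn)
    if (f_variant == "product") {
      m$f_measure <- safe_div(m$precision * m$sensitivity,
                              m$precision + m$sensitivity)
    }
    m
  }
  if (mode == "binary") {
    rep_ <- ovr(positive + 1L)
    rep_$mode <- "binary"
    class(rep_) <- "metrics_report"
    return(rep_)
  }
  per <- lapply(seq_len(n_classes), ovr)
  if (mode == "per-class") {
    df <- do.call(rbind, lapply(per, as.data.frame))
    df <- cbind(class = seq_len(n_classes) - 1L, df)
    return(df)
  }
  avg <- lapply(names(per[[1]]), function(nm) {
    mean(vapply(per, `[[`, numeric(1), nm))
  })
  names(avg) <- names(per[[1]])
  avg$mode <- "macro"
  class(avg) <- "metrics_report"
  avg
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> (%s)\n", x$mode))
  nums <- x[setdiff(names(x), "mode")]
  for (nm in names(nums)) cat(sprintf("  %-12s %.6f\n", nm, nums[[nm]]))
  invisible(x)
}

#' One-vs-rest ROC curve and area
#'
#' Sweeps the decision threshold over the unique scores of class `class`,
#' producing (FPR, TPR) points from (0,0) to (1,1) with FPR monotone
#' non-decreasing; the area is the trapezoid-rule integral.
#'
#' @param y_true Integer labels 0:2 (both the positive class and at least one
#'   other must be present).
#' @param scores Probability matrix (columns = classes 0:2) or a numeric
#'   vector of scores for the positive class.
#' @param class Positive class label (default 2).
#' @return List with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_points <- function(y_true, scores, class = 2L) {
  s <- if (is.matrix(scores)) scores[, class + 1L] else as.numeric(scores)
  pos <- y_true == class
  if (all(pos) || !any(pos)) {
    stopf("roc_points(): need both positive and negative samples")
  }
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}
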