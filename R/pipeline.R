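# End-to-end pipeline ---------------------------------------------------------

#' Default pipeline configuration
#'
#' A single nested list drives a full run: simulate -> clean -> split ->
#' feature extraction (PCA on the sensor columns) -> HTLSS wrapper feature
#' selection -> TriNet training -> evaluation -> ledger. Any element can be
#' overridden via `...` (named sublists are merged).
#'
#' @param ... Overrides merged over the defaults, e.g.
#'   `run_config(split = list(learning_rate = 0.8))`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(n_per_class = c(690L, 682L, 667L), separation = 2.0,
                    missing_rate = 0.01),
    preprocess = list(policy = "drop"),
    split = list(learning_rate = 0.7, stratified = FALSE),
    features = list(variance_fraction = 0.99, lambda_eig = NULL),
    select = list(pop_size = 12L, max_iters = 15L, alpha = 0.01),
    trinet = list(epochs = 40L, batch_size = 32L, lr = 0.1, hidden = 8L,
                  fusion = "soft"),
    ledger = list(max_events = 25L),
    paths = list(out_dir = NULL)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      overrides[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full fall-detection pipeline
#'
#' Executes every stage in order on seeded synthetic cStick data and returns
#' an aggregated report. Stage artifacts (tables, mask, metrics, ledger) are
#' written under `config$paths$out_dir` when it is set.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `run_report` list: `metrics` (macro [metrics_report()]),
#'   `confusion`, `mask`, `selected_features`, `auc_fall` (one-vs-rest ROC
#'   area for the actual-fall class), `ledger` (verified chain of detected
#'   fall events), `sizes`, `seed`, `config`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  say("stage simulate: %d records", sum(config$simulate$n_per_class))
  tab <- gen_cstick_table(config$simulate$n_per_class,
                          separation = config$simulate$separation,
                          seed = seed)
  if (config$simulate$missing_rate > 0) {
    tab <- inject_missing(tab, config$simulate$missing_rate, seed = seed + 1L)
  }

  say("stage preprocess: policy %s", config$preprocess$policy)
  viol <- validate_schema(tab)
  clean <- impute_nulls(tab, config$preprocess$policy)
  split <- split_dataset(clean, learning_rate = config$split$learning_rate,
                         stratified = config$split$stratified,
                         seed = seed + 2L)

  say("stage features: PCA on sensor columns")
  xtr_raw <- as.matrix(as.data.frame(split$train)[, CSTICK_FEATURES])
  xte_raw <- as.matrix(as.data.frame(split$test)[, CSTICK_FEATURES])
  pca <- pca_fit(xtr_raw, variance_fraction = config$features$variance_fraction,
                 lambda_eig = config$features$lambda_eig)
  xtr <- pca_transform(xtr_raw, pca)
  xte <- pca_transform(xte_raw, pca)
  ytr <- split$train$decision
  yte <- split$test$decision

  say("stage select: HTLSS wrapper over %d components", ncol(xtr))
  sel_cfg <- hsstl_config(dim = ncol(xtr), pop_size = config$select$pop_size,
                          max_iters = config$select$max_iters,
                          seed = seed + 3L)
  sel <- select_features(xtr, ytr, config = sel_cfg,
                         alpha = config$select$alpha)

  say("stage train: TriNet on %d features, %d epochs",
      sum(sel$mask), config$trinet$epochs)
  tn_cfg <- trinet_config(epochs = config$trinet$epochs,
                          batch_size = config$trinet$batch_size,
                          lr = config$trinet$lr,
                          hidden = config$trinet$hidden,
                          fusion = config$trinet$fusion,
                          seed = seed + 4L)
  model <- train_trinet(xtr[, sel$mask, drop = FALSE], ytr, tn_cfg)

  say("stage evaluate: %d test records", nrow(xte))
  pred <- fuse_predict(model, xte[, sel$mask, drop = FALSE])
  cm <- confusion_matrix(yte, pred$class)
  metrics <- metrics_report(cm, mode = "macro")
  roc <- roc_points(yte, pred$probs, class = 2L)

  say("stage ledger: recording detected fall events")
  chain <- ledger_new(timestamp = "1970-01-01T00:00:00Z")
  fall_idx <- which(pred$class == 2L)
  keep <- head(fall_idx, config$ledger$max_events)
  for (i in keep) {
    ev <- fall_event(subject_id = sprintf("test-%04d", i),
                     predicted_class = pred$class[i],
                     confidence = max(pred$probs[i, ]),
                     timestamp = sprintf("1970-01-01T00:00:%02dZ",
                                         match(i, keep) %% 60))
    chain <- ledger_append(chain, ev)
  }
  verification <- ledger_verify(chain)

  report <- structure(
    list(metrics = metrics, confusion = cm, mask = sel$mask,
         selected_features = sel$features, auc_fall = roc$auc,
         ledger = chain, ledger_ok = verification$ok,
         schema_violations = nrow(viol),
         sizes = list(n = nrow(clean), train = nrow(split$train),
                      test = nrow(split$test)),
         seed = seed, config = config),
    class = "run_report"
  )
  if (!is.null(config$paths$out_dir)) {
    dir.create(config$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cstick(split$train, file.path(config$paths$out_dir, "train.csv"))
    write_cstick(split$test, file.path(config$paths$out_dir, "test.csv"))
    ledger_write(chain, file.path(config$paths$out_dir, "ledger.jsonl"))
    jsonlite::write_json(
      list(metrics = unclass(metrics)[setdiff(names(metrics), "mode")],
           confusion = unclass(cm), sizes = report$sizes, seed = seed),
      file.path(config$paths$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d | n = %d (train %d / test %d)\n",
              x$seed, x$sizes$n, x$sizes$train, x$sizes$test))
  cat(sprintf("selected features: %s\n",
              paste(x$selected_features, collapse = ", ")))
  cat(sprintf("macro accuracy %.4f | macro F %.4f | fall-class AUC %.4f\n",
              x$metrics$accuracy, x$metrics$f_measure, x$auc_fall))
  cat(sprintf("ledger: %d block(s), %s\n", length(x$ledger),
              if (x$ledger_ok) "verified" else "INTEGRITY VIOLATION"))
  invisible(x)
}

#' Exploratory summary of a sensor table
#'
#' Pearson correlation matrix over the numeric sensor columns (constant
#' columns yield 0 with a warning), class proportions, and per-column
#' summaries — the numeric content behind the usual correlation-heatmap and
#' class-pie views.
#'
#' @param table A `cstick_table` with at least 2 rows.
#' @return List with `correlation` (symmetric, unit diagonal),
#'   `class_proportions` (sums to 1), `column_summary` (data.frame of mean,
#'   sd, min, max per column).
#' @export
eda_summary <- function(table) {
  df <- as.data.frame(table)
  if (nrow(df) < 2) stopf("eda_summary(): need at least 2 rows")
  num <- df[, CSTICK_FEATURES, drop = FALSE]
  sds <- vapply(num, function(x) sd(x, na.rm = TRUE), numeric(1))
  cmat <- suppressWarnings(cor(num, use = "pairwise.complete.obs"))
  if (any(sds == 0)) {
    warning("eda_summary(): constant column(s); correlations set to 0",
            call. = FALSE)
    cmat[is.na(cmat)] <- 0
    diag(cmat) <- 1
  }
  props <- as.numeric(table(factor(df$decision, levels = 0:2))) / nrow(df)
  names(props) <- c("no_fall", "slip_predicted", "fall")
  summ <- data.frame(
    column = names(num),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1)),
    sd = sds,
    min = vapply(num, function(x) min(x, na.rm = TRUE), numeric(1)),
    max = vapply(num, function(x) max(x, na.rm = TRUE), numeric(1)),
    missing = vapply(num, function(x) sum(is.na(x)), numeric(1)),
    row.names = NULL
  )
  list(correlation = cmat, class_proportions = props, column_summary = summ)
}

#' Epoch-budget study
#'
#' Trains TriNet once per epoch budget on identical seeded data (same
#' simulated table, split, PCA and selected features) and reports the macro
#' metric suite per budget, mirroring the usual 50-vs-100-epoch comparison.
#'
#' @param config A [run_config()].
#' @param epoch_list At least two epoch budgets.
#' @return data.frame: one row per budget with the nine macro metrics.
#' @export
epoch_study <- function(config = run_config(), epoch_list = c(50L, 100L)) {
  if (length(epoch_list) < 2) stopf("epoch_study(): need at least 2 budgets")
  seed <- config$seed
  tab <- gen_cstick_table(config$simulate$n_per_class,
                          separation = config$simulate$separation,
                          seed = seed)
  split <- split_dataset(tab, learning_rate = config$split$learning_rate,
                         seed = seed + 2L)
  xtr_raw <- as.matrix(as.data.frame(split$train)[, CSTICK_FEATURES])
  xte_raw <- as.matrix(as.data.frame(split$test)[, CSTICK_FEATURES])
  pca <- pca_fit(xtr_raw, variance_fraction = config$features$variance_fraction)
  xtr <- pca_transform(xtr_raw, pca)
  xte <- pca_transform(xte_raw, pca)
  rows <- lapply(epoch_list, function(ep) {
    cfg <- trinet_config(epochs = ep, batch_size = config$trinet$batch_size,
                         lr = config$trinet$lr, hidden = config$trinet$hidden,
                         seed = seed + 4L)
    model <- train_trinet(xtr, split$train$decision, cfg)
    pred <- fuse_predict(model, xte)
    m <- metrics_report(confusion_matrix(split$test$decision, pred$class))
    data.frame(epochs = ep,
               as.data.frame(unclass(m)[setdiff(names(m), "mode")]))
  })
  do.call(rbind, rows)
}
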