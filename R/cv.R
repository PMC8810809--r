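#' Stratified k-fold cross-validation of the glucose network
#'
#' Splits the records into `k` folds stratified on the diabetes label (each
#' fold's class ratio within one sample of the global ratio), trains a fresh
#' network on each training portion — feature scaling refit inside every
#' fold, so no information leaks from the validation rows — predicts the
#' held-out fold, thresholds at `threshold` mg/dL, and pools the per-fold
#' confusion counts.
#'
#' @param records Observation tibble with `glucose_ref` and `dm_label`.
#' @param k Number of folds (>= 2, default 10).
#' @param config A [training_config()]; fold `i` trains with seed
#'   `config$seed + i` so folds are independent but reproducible.
#' @param features Feature columns to train on.
#' @param threshold Diagnostic threshold (mg/dL).
#'
#' @return An object of class `sdnn_cv`: `folds` (list of per-fold results
#'   with validation indices, predictions, `confusion` and `metrics`),
#'   `pooled_confusion`, `pooled_metrics`, and `assignments` (fold id per
#'   row).
#' @export
#'
#' @examples
#' cfg <- optical_config(seed = 11)
#' ds <- make_dataset(generate_population(60, cfg), 1, glucose_sampler(), cfg)
#' cv <- sdnn_kfold_cv(ds, k = 3, config = training_config(epochs = 20))
#' tidy(cv)
sdnn_kfold_cv <- function(records, k = 10L, config = training_config(),
                          features = model_fields(), threshold = 126) {
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be >= 2.")
  n <- nrow(records)
  if (n < k) abort("Dataset must have at least `k` rows.")

  set.seed(config$seed)
  labels <- records$dm_label
  fold_of <- integer(n)
  if (length(unique(labels)) < 2L) {
    warn("Only one class present; falling back to unstratified folds.")
    fold_of <- sample(rep(seq_len(k), length.out = n))
  } else {
    # Per class, every fold gets the integer share and the remainder goes
    # to the currently least-loaded folds, so per-fold class counts differ
    # by at most one sample and total fold sizes stay within one of each
    # other.
    load <- integer(k)
    classes <- names(sort(table(labels), decreasing = TRUE))
    for (cl in classes) {
      idx <- sample(which(labels == as.numeric(cl)))
      q <- length(idx) %/% k
      r <- length(idx) %% k
      counts <- rep(q, k)
      if (r > 0) {
        extra <- order(load, sample.int(k))[seq_len(r)]
        counts[extra] <- counts[extra] + 1L
      }
      fold_of[idx] <- rep(seq_len(k), counts)
      load <- load + counts
    }
  }

  folds <- purrr::map(seq_len(k), function(i) {
    val <- which(fold_of == i)
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    fit <- sdnn_train(records[-val, , drop = FALSE], cfg_i, features)
    pred <- predict(fit, records[val, , drop = FALSE])
    pred_label <- if (identical(config$output, "binary")) {
      as.integer(pred >= 0.5)
    } else {
      classify_dm(pred, threshold)
    }
    cm <- confusion_matrix(truth = labels[val], predicted = pred_label)
    list(
      fold_index = i,
      val_idx = val,
      predicted = pred,
      reference = records$glucose_ref[val],
      errors = if (identical(config$output, "binary")) NULL else
        pred - records$glucose_ref[val],
      confusion = cm,
      metrics = confusion_metrics(cm)
    )
  })

  pooled <- Reduce(`+`, purrr::map(folds, "confusion"))
  class(pooled) <- "confusion_matrix"
  structure(
    list(
      folds = folds,
      k = k,
      assignments = fold_of,
      threshold = threshold,
      pooled_confusion = pooled,
      pooled_metrics = confusion_metrics(pooled)
    ),
    class = "sdnn_cv"
  )
}

#' @export
print.sdnn_cv <- function(x, ...) {
  cat("<sdnn_cv>", x$k, "stratified folds, threshold", x$threshold, "mg/dL\n")
  m <- x$pooled_metrics
  cat(sprintf("  pooled: accuracy %.3f | precision %.3f | sensitivity %.3f | specificity %.3f\n",
              m$accuracy, m$precision, m$sensitivity, m$specificity))
  invisible(x)
}

#' @rdname sdnn_kfold_cv
#' @param x An `sdnn_cv` object.
#' @param ... Unused.
#' @method tidy sdnn_cv
#' @export
tidy.sdnn_cv <- function(x, ...) {
  purrr::map(x$folds, function(f) {
    dplyr::bind_cols(tibble(fold = f$fold_index, n_val = length(f$val_idx)),
                     f$metrics)
  }) |> list_rbind()
}

#' @rdname sdnn_kfold_cv
#' @method glance sdnn_cv
#' @export
glance.sdnn_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(k = x$k, n = length(x$assignments)),
    x$pooled_metrics
  )
}
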