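#' Exclusion-based feature-group importance
#'
#' Importance of a feature group is measured by retraining the model with
#' that group's columns removed entirely (the network input narrows) and
#' recording the drop in the evaluation metric relative to the full-feature
#' baseline. Raw drops are floored at zero and normalized to sum to one.
#' The canonical grouping contrasts the three mbNIR channels against the
#' six personal medical features.
#'
#' @param train_records Training observation tibble.
#' @param test_records Held-out observation tibble the metric is computed
#'   on.
#' @param groups Named list of character vectors partitioning the feature
#'   set (every feature in exactly one group, at least two groups).
#' @param config A [training_config()] (the trainer is deterministic given
#'   its seed, so drops are attributable to the exclusion).
#' @param metric Function `(truth_labels, predicted_glucose) -> number`
#'   where larger is better; defaults to DM-classification accuracy at the
#'   126 mg/dL threshold.
#' @param features Full feature set being partitioned.
#'
#' @return An object of class `feature_importance`: tibble with one row per
#'   group (`group`, `metric_excluded`, `drop_raw`, `importance`), plus the
#'   `baseline` metric.
#' @export
#'
#' @examples
#' \donttest{
#' cfg <- optical_config(seed = 8)
#' tr <- make_dataset(generate_population(80, cfg), 1, glucose_sampler(), cfg)
#' te <- make_dataset(generate_population(40, optical_config(seed = 9)), 1,
#'                    glucose_sampler(), optical_config(seed = 9))
#' feature_importance_by_exclusion(tr, te,
#'   config = training_config(epochs = 50))
#' }
feature_importance_by_exclusion <- function(train_records, test_records,
                                            groups = list(
                                              mbNIR = c("nir_1", "nir_2", "nir_3"),
                                              PMF = pmf_fields()
                                            ),
                                            config = training_config(),
                                            metric = NULL,
                                            features = model_fields()) {
  all_grouped <- unlist(groups, use.names = FALSE)
  if (length(groups) < 2L) {
    abort("Need at least two groups; a single all-covering group has no baseline contrast.")
  }
  if (!setequal(all_grouped, features) || anyDuplicated(all_grouped)) {
    abort("`groups` must partition the feature set exactly.")
  }
  if (is.null(metric)) {
    metric <- function(truth, pred) mean(as.integer(pred >= 126) == truth)
  }

  evaluate_with <- function(feats) {
    fit <- sdnn_train(train_records, config, features = feats)
    pred <- predict(fit, test_records)
    metric(test_records$dm_label, pred)
  }

  baseline <- evaluate_with(features)
  rows <- purrr::imap(groups, function(cols, nm) {
    kept <- setdiff(features, cols)
    m <- evaluate_with(kept)
    tibble(group = nm, metric_excluded = m, drop_raw = max(baseline - m, 0))
  }) |> list_rbind()

  total <- sum(rows$drop_raw)
  rows$importance <- if (total > 0) rows$drop_raw / total else
    rep(1 / nrow(rows), nrow(rows))
  structure(
    list(table = rows, baseline = baseline, metric_name = "accuracy"),
    class = "feature_importance"
  )
}

#' @export
print.feature_importance <- function(x, ...) {
  cat("<feature_importance> baseline metric:", signif(x$baseline, 4), "\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @method tidy feature_importance
#' @export
tidy.feature_importance <- function(x, ...) x$table
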