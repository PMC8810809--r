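#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (predict positive
#' when `score >= t`), producing the ordered (FPR, TPR) staircase from
#' (0, 0) to (1, 1). The AUC is the trapezoidal area under that staircase,
#' which equals the normalized Mann-Whitney U statistic: the probability
#' that a random positive outscores a random negative, ties counted 1/2.
#'
#' @param scores Numeric scores (higher = more positive), e.g. predicted
#'   glucose.
#' @param labels Binary 0/1 truth labels; both classes must be present.
#' @return An object of class `roc_curve`: `points` tibble
#'   (`threshold, fpr, tpr`) and `auc`.
#' @export
#'
#' @examples
#' roc_curve(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC needs both classes present in `labels`.")
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map(thresholds, function(t) {
    pred <- scores >= t
    c(threshold = t,
      fpr = sum(pred & labels == 0L) / n_neg,
      tpr = sum(pred & labels == 1L) / n_pos)
  })
  points <- bind_rows(
    tibble(threshold = Inf, fpr = 0, tpr = 0),
    as_tibble(do.call(rbind, pts))
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Pair-counting AUC (Mann-Whitney)
#'
#' Exhaustive count over all positive-negative pairs: a pair scores 1 when
#' the positive outscores the negative, 1/2 on a tie. Quadratic in n; used
#' as the independent cross-check of the sweep-based [roc_curve()] AUC.
#'
#' @inheritParams roc_curve
#' @return The AUC as a single number.
#' @export
auc_pair_count <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("AUC needs both classes present.")
  }
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve>", x$n_pos, "positives /", x$n_neg, "negatives, AUC =",
      signif(x$auc, 4), "\n")
  invisible(x)
}

#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
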