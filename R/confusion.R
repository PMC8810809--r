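#' Build a 2x2 confusion matrix
#'
#' Positive class is "High" (glucose at or above the diagnostic threshold).
#' Either supply the four counts directly, or `truth` and `predicted` 0/1
#' vectors to be tabulated.
#'
#' @param tp,fp,fn,tn Non-negative counts (true/false positives/negatives).
#' @param truth,predicted Binary 0/1 vectors of equal length (alternative
#'   interface; ignored when counts are given).
#' @return A classed named numeric vector `c(tp, fp, fn, tn)`.
#' @export
#'
#' @examples
#' confusion_matrix(tp = 102, fp = 2, fn = 4, tn = 293)
#' confusion_matrix(truth = c(1, 0, 1), predicted = c(1, 0, 0))
confusion_matrix <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                             truth = NULL, predicted = NULL) {
  if (is.null(tp)) {
    if (is.null(truth) || is.null(predicted)) {
      abort("Supply either the four counts or `truth` and `predicted`.")
    }
    if (length(truth) != length(predicted)) {
      abort("`truth` and `predicted` must have equal length.")
    }
    tp <- sum(truth == 1 & predicted == 1)
    fp <- sum(truth == 0 & predicted == 1)
    fn <- sum(truth == 1 & predicted == 0)
    tn <- sum(truth == 0 & predicted == 0)
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("Confusion counts must be finite and non-negative.")
  }
  structure(as.numeric(counts), names = names(counts),
            class = "confusion_matrix")
}

#' Read a printed 2x2 table under the rows-as-predicted convention
#'
#' Clinical papers often print DM confusion tables as a High/Low square.
#' This helper ingests such a table taking rows as the predicted class and
#' columns as the truth — the convention under which the standard metric
#' definitions (sensitivity = TP / column total, precision = TP / row
#' total) reconcile with typically printed percentages.
#'
#' @param tbl 2x2 numeric matrix, rows and columns ordered High then Low.
#' @return A [confusion_matrix()].
#' @export
#'
#' @examples
#' confusion_from_square(rbind(c(102, 2), c(4, 293)))
confusion_from_square <- function(tbl) {
  tbl <- as.matrix(tbl)
  stopifnot(nrow(tbl) == 2L, ncol(tbl) == 2L)
  confusion_matrix(tp = tbl[1, 1], fp = tbl[1, 2],
                   fn = tbl[2, 1], tn = tbl[2, 2])
}

#' Accuracy, precision, sensitivity and specificity from a confusion matrix
#'
#' `accuracy = (tp+tn)/total`, `precision = tp/(tp+fp)`,
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`. A ratio with a
#' zero denominator is reported as `NA` with a warning, never as zero.
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble with the four proportions and `total`.
#' @export
#'
#' @examples
#' confusion_metrics(confusion_matrix(tp = 102, fp = 2, fn = 4, tn = 293))
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  total <- tp + fp + fn + tn
  if (total == 0) abort("Confusion matrix is all-zero; metrics undefined.")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined (zero denominator); reported as NA."))
      return(NA_real_)
    }
    num / den
  }
  tibble(
    accuracy = (tp + tn) / total,
    precision = ratio(tp, tp + fp, "precision"),
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    total = total
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (positive = High)\n")
  m <- rbind(c(x[["tp"]], x[["fp"]]), c(x[["fn"]], x[["tn"]]))
  dimnames(m) <- list(predicted = c("High", "Low"), truth = c("High", "Low"))
  print(m)
  invisible(x)
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble(tp = x[["tp"]], fp = x[["fp"]], fn = x[["fn"]], tn = x[["tn"]]),
    confusion_metrics(x)
  )
}
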