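#' Clarke Error Grid plot
#'
#' Scatter of predicted vs reference glucose colored by zone, with the
#' identity and +/- 20% accuracy lines marking zone A.
#'
#' @param report A [ceg_report()].
#' @return A ggplot object.
#' @export
plot_ceg <- function(report) {
  stopifnot(inherits(report, "ceg_report"))
  pts <- report$points
  lim <- data.frame(x = c(0, 450))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$ref, y = .data$pred,
                                    colour = .data$zone)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "solid",
                         colour = "grey40") +
    ggplot2::geom_abline(slope = 1.2, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = 0.8, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = lim$x, ylim = lim$x) +
    ggplot2::labs(x = "Reference glucose (mg/dL)",
                  y = "Predicted glucose (mg/dL)",
                  colour = "Zone", title = "Clarke Error Grid")
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias and 95% limits of
#' agreement.
#'
#' @param ba A [bland_altman()] report.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  stopifnot(inherits(ba, "bland_altman"))
  unit <- if (ba$mode == "percent") "%" else "mg/dL"
  ggplot2::ggplot(ba$differences,
                  ggplot2::aes(x = .data$mean_pair, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "indianred") +
    ggplot2::labs(x = "Mean of reference and prediction (mg/dL)",
                  y = paste0("Difference (", unit, ")"),
                  title = "Bland-Altman agreement")
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}

#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) plot_bland_altman(object)

#' @method autoplot ceg_report
#' @export
autoplot.ceg_report <- function(object, ...) plot_ceg(object)

#' Plot a monitoring time series
#'
#' True glucose and the low-pass-filtered prediction over session time.
#'
#' @param ts Tibble from [run_monitor()].
#' @return A ggplot object.
#' @export
plot_monitor <- function(ts) {
  long <- tidyr::pivot_longer(
    ts[, c("time_min", "glucose", "predicted_filtered")],
    cols = c("glucose", "predicted_filtered"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Glucose (mg/dL)", colour = NULL)
}
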