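#' Bland-Altman agreement between a reference and a test method
#'
#' Differences are `pred - ref` in absolute mode (mg/dL) or
#' `100 * (pred - ref) / ref` in percent mode (the default, matching the
#' relative +/- 15% accuracy convention of glucose meters). The bias is the
#' mean difference and the 95% limits of agreement are
#' `bias +/- 1.96 * SD` with the sample (n-1) standard deviation.
#'
#' @param ref Reference series (mg/dL), length >= 2.
#' @param pred Test-method series, same length.
#' @param mode `"percent"` or `"absolute"`.
#' @return An object of class `bland_altman`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `mode`, `n`, and the per-pair `differences`
#'   tibble (with the pair means for plotting).
#' @export
#'
#' @examples
#' ba <- bland_altman(c(100, 150, 200, 250), c(90, 160, 190, 260),
#'                    mode = "absolute")
#' ba$loa_high
bland_altman <- function(ref, pred, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  if (length(ref) != length(pred)) abort("`ref` and `pred` must have equal length.")
  if (length(ref) < 2L) abort("Need at least 2 pairs.")
  if (mode == "percent" && any(ref == 0)) {
    abort("Percent mode requires all reference values nonzero.")
  }
  d <- if (mode == "percent") 100 * (pred - ref) / ref else pred - ref
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(
      bias = bias,
      sd_diff = s,
      loa_low = bias - 1.96 * s,
      loa_high = bias + 1.96 * s,
      mode = mode,
      n = length(d),
      differences = tibble(mean_pair = (ref + pred) / 2, difference = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else "mg/dL"
  cat("<bland_altman>", x$n, "pairs,", x$mode, "differences\n")
  cat(sprintf("  bias %.3f %s | 95%% LoA [%.3f, %.3f] %s\n",
              x$bias, unit, x$loa_low, x$loa_high, unit))
  invisible(x)
}

#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
         loa_high = x$loa_high, mode = x$mode, n = x$n)
}
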