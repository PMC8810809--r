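#' ISO 15197:2013 accuracy check for a glucose measurement series
#'
#' The point-of-care glucometer standard's two system-accuracy criteria:
#' \enumerate{
#'   \item at least 95% of results within +/- 15 mg/dL of the laboratory
#'     reference when the reference is below 100 mg/dL, and within +/- 15%
#'     when it is 100 mg/dL or above (pooled over all pairs, each judged at
#'     its own reference-dependent limit; the boundary is inclusive);
#'   \item at least 99% of results inside error-grid zones A and B
#'     (evaluated here on the Clarke grid).
#' }
#'
#' @param ref Laboratory reference glucose (mg/dL), > 0.
#' @param pred Meter / model glucose (mg/dL), >= 0.
#' @return An object of class `iso15197_report` with the per-stratum and
#'   pooled within-limit fractions, the zone A+B fraction, and the
#'   `criterion1_pass`, `criterion2_pass`, `overall_pass` booleans.
#' @export
#'
#' @examples
#' iso15197_check(c(90, 150, 250), c(100, 160, 240))
iso15197_check <- function(ref, pred) {
  if (length(ref) != length(pred)) abort("`ref` and `pred` must have equal length.")
  if (length(ref) < 1L) abort("Need at least one pair.")
  if (any(ref <= 0)) abort("Reference glucose must be > 0.")
  low <- ref < 100
  within <- ifelse(low, abs(pred - ref) <= 15,
                   abs(pred - ref) <= 0.15 * ref)
  zones <- ceg_zone(ref, pred)
  frac_ab <- mean(zones %in% c("A", "B"))
  frac_within <- mean(within)
  structure(
    list(
      n = length(ref),
      frac_within = frac_within,
      frac_within_low = if (any(low)) mean(within[low]) else NA_real_,
      frac_within_high = if (any(!low)) mean(within[!low]) else NA_real_,
      frac_zone_ab = frac_ab,
      criterion1_pass = frac_within >= 0.95,
      criterion2_pass = frac_ab >= 0.99,
      overall_pass = frac_within >= 0.95 && frac_ab >= 0.99
    ),
    class = "iso15197_report"
  )
}

#' @export
print.iso15197_report <- function(x, ...) {
  cat("<iso15197_report>", x$n, "pairs\n")
  cat(sprintf("  within limits: %.1f%% (ref<100: %s, ref>=100: %s) -> criterion 1 %s\n",
              100 * x$frac_within,
              ifelse(is.na(x$frac_within_low), "n/a",
                     sprintf("%.1f%%", 100 * x$frac_within_low)),
              ifelse(is.na(x$frac_within_high), "n/a",
                     sprintf("%.1f%%", 100 * x$frac_within_high)),
              ifelse(x$criterion1_pass, "PASS", "FAIL")))
  cat(sprintf("  Clarke zones A+B: %.1f%% -> criterion 2 %s\n",
              100 * x$frac_zone_ab,
              ifelse(x$criterion2_pass, "PASS", "FAIL")))
  cat("  overall:", ifelse(x$overall_pass, "PASS", "FAIL"), "\n")
  invisible(x)
}

#' @method glance iso15197_report
#' @export
glance.iso15197_report <- function(x, ...) {
  tibble(
    n = x$n, frac_within = x$frac_within,
    frac_within_low = x$frac_within_low,
    frac_within_high = x$frac_within_high,
    frac_zone_ab = x$frac_zone_ab,
    criterion1_pass = x$criterion1_pass,
    criterion2_pass = x$criterion2_pass,
    overall_pass = x$overall_pass
  )
}
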