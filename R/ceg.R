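#' Clarke Error Grid zone assignment
#'
#' Assigns each (reference, predicted) glucose pair to one of the classical
#' Clarke zones. Zone A is clinically accurate (within 20% of the
#' reference, or both values in the hypoglycemic range <= 70 mg/dL); E is a
#' critical error (treatment for the opposite state); C would trigger
#' unnecessary correction; D is a dangerous failure to detect; everything
#' else is the benign zone B. Rules, applied with precedence
#' A > E > C > D > B:
#' \itemize{
#'   \item A: (ref <= 70 and pred <= 70) or 0.8*ref <= pred <= 1.2*ref
#'   \item E: (ref >= 180 and pred <= 70) or (ref <= 70 and pred >= 180)
#'   \item C: (70 <= ref <= 290 and pred >= ref + 110) or
#'     (130 <= ref <= 180 and pred <= (7/5)*ref - 182)
#'   \item D: (ref >= 240 and 70 <= pred <= 180) or
#'     (ref <= 175/3 and 70 <= pred <= 180) or
#'     (175/3 <= ref <= 70 and pred >= (6/5)*ref)
#' }
#'
#' @param ref Reference glucose (mg/dL), > 0.
#' @param pred Predicted glucose (mg/dL), >= 0.
#' @return Character vector of zones in `{"A","B","C","D","E"}`.
#' @export
#'
#' @examples
#' ceg_zone(c(100, 50, 250, 150), c(100, 250, 120, 270))
ceg_zone <- function(ref, pred) {
  if (length(ref) != length(pred)) abort("`ref` and `pred` must have equal length.")
  if (any(!is.finite(ref)) || any(!is.finite(pred))) {
    abort("`ref` and `pred` must be finite.")
  }
  if (any(ref <= 0) || any(pred < 0)) {
    abort("Require ref > 0 and pred >= 0 (mg/dL).")
  }
  zone_a <- (ref <= 70 & pred <= 70) | (pred >= 0.8 * ref & pred <= 1.2 * ref)
  zone_e <- (ref >= 180 & pred <= 70) | (ref <= 70 & pred >= 180)
  zone_c <- (ref >= 70 & ref <= 290 & pred >= ref + 110) |
    (ref >= 130 & ref <= 180 & pred <= (7 / 5) * ref - 182)
  zone_d <- (ref >= 240 & pred >= 70 & pred <= 180) |
    (ref <= 175 / 3 & pred >= 70 & pred <= 180) |
    (ref >= 175 / 3 & ref <= 70 & pred >= (6 / 5) * ref)
  out <- rep("B", length(ref))
  out[zone_d] <- "D"
  out[zone_c] <- "C"
  out[zone_e] <- "E"
  out[zone_a] <- "A"
  out
}

#' Clarke Error Grid zone counts and fractions
#'
#' @param ref,pred Paired glucose series (mg/dL).
#' @return An object of class `ceg_report`: tibble of per-point assignments
#'   (`ref, pred, zone`) plus `zone_counts` and `zone_fractions` over the
#'   five zones.
#' @export
#'
#' @examples
#' ceg_report(c(90, 200, 55), c(95, 180, 150))
ceg_report <- function(ref, pred) {
  zones <- ceg_zone(ref, pred)
  counts <- table(factor(zones, levels = c("A", "B", "C", "D", "E")))
  structure(
    list(
      points = tibble(ref = ref, pred = pred, zone = zones),
      zone_counts = setNames(as.integer(counts), names(counts)),
      zone_fractions = setNames(as.numeric(counts) / length(zones),
                                names(counts))
    ),
    class = "ceg_report"
  )
}

#' @export
print.ceg_report <- function(x, ...) {
  cat("<ceg_report>", nrow(x$points), "points\n")
  print(rbind(count = x$zone_counts,
              fraction = round(x$zone_fractions, 4)))
  invisible(x)
}

#' @method tidy ceg_report
#' @export
tidy.ceg_report <- function(x, ...) {
  tibble(
    zone = names(x$zone_counts),
    count = x$zone_counts,
    fraction = x$zone_fractions
  )
}

#' Write per-point Clarke zone assignments as CSV
#'
#' @param report A [ceg_report()].
#' @param path File path; columns `ref,pred,zone`.
#' @return `path`, invisibly.
#' @export
write_ceg <- function(report, path) {
  stopifnot(inherits(report, "ceg_report"))
  write.csv(report$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
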