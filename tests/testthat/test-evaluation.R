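# Independent scalar re-coding of the Clarke zone rules, used as the
# brute-force oracle against the vectorized implementation.
clarke_oracle <- function(ref, pred) {
  if (ref <= 70 && pred <= 70) return("A")
  if (pred >= 0.8 * ref && pred <= 1.2 * ref) return("A")
  if ((ref >= 180 && pred <= 70) || (ref <= 70 && pred >= 180)) return("E")
  if (ref >= 70 && ref <= 290 && pred >= ref + 110) return("C")
  if (ref >= 130 && ref <= 180 && pred <= (7 / 5) * ref - 182) return("C")
  if (ref >= 240 && pred >= 70 && pred <= 180) return("D")
  if (ref <= 175 / 3 && pred >= 70 && pred <= 180) return("D")
  if (ref >= 175 / 3 && ref <= 70 && pred >= (6 / 5) * ref) return("D")
  "B"
}

test_that("confusion metrics follow their definitions and edge rules", {
  cm <- confusion_matrix(tp = 10, fp = 0, fn = 0, tn = 10)
  m <- confusion_metrics(cm)
  expect_equal(unlist(m[, 1:4]),
               c(accuracy = 1, precision = 1, sensitivity = 1, specificity = 1))

  worst <- confusion_metrics(confusion_matrix(tp = 0, fp = 5, fn = 5, tn = 0))
  expect_equal(worst$accuracy, 0)
  expect_equal(worst$sensitivity, 0)
  expect_equal(worst$specificity, 0)

  # zero denominator -> NA with warning, never silently 0
  expect_warning(
    m2 <- confusion_metrics(confusion_matrix(tp = 0, fp = 0, fn = 3, tn = 7)),
    "precision"
  )
  expect_true(is.na(m2$precision))
  expect_error(confusion_metrics(confusion_matrix(tp = 0, fp = 0, fn = 0, tn = 0)),
               "all-zero")

  # tabulation interface agrees with direct counts
  cm2 <- confusion_matrix(truth = c(1, 1, 0, 0, 1), predicted = c(1, 0, 0, 1, 1))
  expect_identical(unclass(cm2)[1:4], c(tp = 2, fp = 1, fn = 1, tn = 1))
})

test_that("Clarke zone assignment matches its anchors and the scalar oracle", {
  expect_identical(ceg_zone(100, 100), "A")
  expect_identical(ceg_zone(50, 250), "E")
  expect_identical(ceg_zone(250, 120), "D")
  expect_identical(ceg_zone(150, 270), "C")

  set.seed(14)
  ref <- runif(4000, 1, 500)
  pred <- runif(4000, 0, 500)
  got <- ceg_zone(ref, pred)
  want <- mapply(clarke_oracle, ref, pred)
  expect_identical(got, unname(want))

  rep_ <- ceg_report(ref, pred)
  expect_equal(sum(rep_$zone_counts), 4000)
  expect_equal(sum(rep_$zone_fractions), 1)
  expect_error(ceg_zone(0, 100), "ref")
  expect_error(ceg_zone(NaN, 100), "finite")
})

test_that("Bland-Altman bias and limits of agreement are exact", {
  # identical methods
  ba0 <- bland_altman(c(80, 120, 200), c(80, 120, 200), mode = "absolute")
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  # hand-computed four-point case: differences -10,+10,-10,+10,
  # sample SD = sqrt(400/3) = 11.547, LoA = +/- 22.632
  ref <- c(100, 100, 100, 100)
  pred <- c(90, 110, 90, 110)
  ba <- bland_altman(ref, pred, mode = "absolute")
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(400 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(400 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_low, -ba$loa_high)

  # percent mode divides by the reference
  bap <- bland_altman(c(100, 200), c(110, 190), mode = "percent")
  expect_equal(bap$differences$difference, c(10, -5))

  # LoA symmetry invariant
  expect_equal(ba$loa_high - ba$bias, ba$bias - ba$loa_low)

  expect_error(bland_altman(1, 1), "at least 2")
  expect_error(bland_altman(c(0, 100), c(1, 99), mode = "percent"), "nonzero")
})

test_that("ROC sweep equals pair counting, with the ties convention", {
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_curve(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)

  set.seed(15)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(1:6, n, replace = TRUE) + rnorm(n, sd = 0.01 * (i %% 2))
    expect_equal(roc_curve(scores, labels)$auc,
                 auc_pair_count(scores, labels))
  }
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")

  # curve is a staircase from (0,0) to (1,1)
  rc <- roc_curve(rnorm(30), rep(0:1, 15))
  expect_equal(rc$points$fpr[1], 0)
  expect_equal(rc$points$tpr[nrow(rc$points)], 1)
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_true(all(diff(rc$points$tpr) >= 0))
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, plogis(scores))
  if (length(unique(labels)) < 2) labels[1:2] <- 0:1
  ours <- roc_curve(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("ISO 15197 limits are reference-dependent and boundary-inclusive", {
  expect_true(iso15197_check(c(80, 150, 300), c(80, 150, 300))$overall_pass)

  # one of ten pairs 16% high -> 90% within -> criterion 1 fails
  ref <- c(rep(100, 9), 200)
  pred <- c(rep(100, 9), 232)
  rep10 <- iso15197_check(ref, pred)
  expect_equal(rep10$frac_within, 0.9)
  expect_false(rep10$criterion1_pass)

  # +/- 15 mg/dL rule below 100
  expect_equal(iso15197_check(90, 104)$frac_within, 1)   # +14
  expect_equal(iso15197_check(90, 106)$frac_within, 0)   # +16
  expect_equal(iso15197_check(90, 105)$frac_within, 1)   # exactly +15: within
  # +/- 15% rule at or above 100
  expect_equal(iso15197_check(200, 230)$frac_within, 1)  # exactly +15%
  expect_equal(iso15197_check(200, 231)$frac_within, 0)
})
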