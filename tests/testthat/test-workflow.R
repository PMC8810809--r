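small_run_config <- function(dir, seed = 9) {
  run_config(
    seed = seed, n_train = 60, n_test = 30,
    training = list(epochs = 150, early_stop_patience = 150),
    k_folds = 3, output_dir = dir
  )
}

test_that("simulate writes disjoint cohorts of the configured sizes", {
  dir <- withr::local_tempdir()
  cfg <- run_config(seed = 2, output_dir = dir)
  res <- run_simulate(cfg)
  expect_equal(nrow(res$train), 401)
  expect_equal(nrow(res$test), 234)
  expect_length(intersect(res$train$person_id, res$test$person_id), 0)
  expect_true(file.exists(res$paths$manifest))

  # same seed -> identical manifest (config hash included)
  dir2 <- withr::local_tempdir()
  cfg2 <- run_config(seed = 2, output_dir = dir2)
  run_simulate(cfg2)
  m1 <- jsonlite::read_json(res$paths$manifest)
  m2 <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  expect_identical(m1$seed, m2$seed)
  expect_identical(m1$files, m2$files)
  # the hash covers everything except the output path
  expect_identical(
    nirglucose:::config_hash(run_config(seed = 2, output_dir = "x")),
    nirglucose:::config_hash(run_config(seed = 2, output_dir = "x"))
  )
})

test_that("train and evaluate produce coherent report files", {
  dir <- withr::local_tempdir()
  cfg <- small_run_config(dir)
  sim <- run_simulate(cfg)
  tr <- run_train(cfg, sim$paths$train)
  expect_true(file.exists(tr$paths$model))
  cvrep <- read.csv(tr$paths$cv_report)
  expect_equal(nrow(cvrep), cfg$k_folds + 1)  # folds + pooled row
  expect_equal(sum(unclass(tr$cv$pooled_confusion)), cfg$n_train)

  ev <- run_evaluate(tr$paths$model, sim$paths$test, cfg)
  expect_equal(sum(ev$ceg$zone_counts), cfg$n_test)
  expect_true(file.exists(ev$paths$evaluation))
  expect_equal(nrow(ev$ceg$points), cfg$n_test)

  # perfect injected pairs pass the ISO check end-to-end
  expect_true(iso15197_check(sim$test$glucose_ref,
                             sim$test$glucose_ref)$overall_pass)
})

test_that("model/data feature mismatch gives a named diagnostic", {
  dir <- withr::local_tempdir()
  cfg <- small_run_config(dir)
  sim <- run_simulate(cfg)
  tr <- run_train(cfg, sim$paths$train)
  broken <- sim$test
  broken$bmi <- NULL
  path <- file.path(dir, "broken.csv")
  write.csv(broken, path, row.names = FALSE)
  expect_error(run_evaluate(tr$paths$model, path, cfg), "bmi")
})

test_that("the low-pass filter is a centered moving average", {
  expect_identical(low_pass_filter(c(5, 7, 9), 1), c(5, 7, 9))
  expect_equal(low_pass_filter(rep(3, 10), 5), rep(3, 10))
  x <- c(1, 2, 3, 4, 5)
  expect_equal(low_pass_filter(x, 3), c(1.5, 2, 3, 4, 4.5))
  expect_error(low_pass_filter(x, 2), "odd")
  expect_error(low_pass_filter(numeric(0), 1), "empty")
})

test_that("monitoring predicts a rise after a meal event", {
  dir <- withr::local_tempdir()
  cfg <- small_run_config(dir, seed = 12)
  sim <- run_simulate(cfg)
  tr <- run_train(cfg, sim$paths$train)
  events <- data.frame(time = 60, event_type = "cake")
  ts <- run_monitor(cfg, tr$paths$model, events, duration = 180)
  expect_true(all(c("predicted", "predicted_filtered") %in% names(ts)))
  before <- mean(ts$predicted_filtered[ts$time_min < 50])
  peak <- max(ts$predicted_filtered[ts$time_min >= 60 & ts$time_min <= 120])
  expect_gt(peak, before)
})

test_that("YAML run configs round-trip and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "n_train: 50", "n_test: 20",
               "training:", "  epochs: 10"), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$seed, 5L)
  expect_equal(cfg$training$epochs, 10)

  writeLines("n_train: 50", path)
  expect_error(read_run_config(path), "seed")
  writeLines(c("seed: 5", "bogus_key: 1"), path)
  expect_error(read_run_config(path), "bogus_key")
})
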