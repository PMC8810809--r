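#' Run configuration for the end-to-end workflow
#'
#' Assembles the seed, generator settings (cohort sizes and the optical
#' model), training hyperparameters and evaluation options driving
#' [run_simulate()], [run_train()], [run_evaluate()] and [run_monitor()].
#' Train and test cohorts are generated from disjoint person pools (the
#' test subjects never enter training).
#'
#' @param seed Master integer seed; the generator, training and fold seeds
#'   derive from it.
#' @param n_train,n_test Cohort sizes (default 401 / 234).
#' @param optical Named list of [optical_config()] overrides.
#' @param sampler Named list of [glucose_sampler()] overrides.
#' @param pmf Named list of [pmf_distributions()] overrides.
#' @param training Named list of [training_config()] overrides.
#' @param threshold Diagnostic threshold (mg/dL).
#' @param ba_mode Bland-Altman mode, `"percent"` or `"absolute"`.
#' @param k_folds Cross-validation folds.
#' @param filter_window Low-pass moving-average window for monitoring
#'   (samples, odd).
#' @param output_dir Directory artifacts are written to.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_train = 401L, n_test = 234L,
                       optical = list(), sampler = list(), pmf = list(),
                       training = list(), threshold = 126,
                       ba_mode = "percent", k_folds = 10L,
                       filter_window = 5L, output_dir = tempdir()) {
  structure(
    list(
      seed = as.integer(seed), n_train = as.integer(n_train),
      n_test = as.integer(n_test), optical = optical, sampler = sampler,
      pmf = pmf, training = training, threshold = threshold,
      ba_mode = ba_mode, k_folds = as.integer(k_folds),
      filter_window = as.integer(filter_window), output_dir = output_dir
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the `seed` key is
#' required so every run is explicitly reproducible.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort("Config file must set an explicit `seed`.")
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, y)
}

# Build the component configs out of a run_config. The test cohort's
# optical seed is offset so its person pool is disjoint from training.
resolve_configs <- function(config, role = c("train", "test")) {
  role <- match.arg(role)
  offset <- if (role == "train") 0L else 7919L
  opt_args <- modifyList(list(seed = config$seed + offset), config$optical)
  list(
    optical = do.call(optical_config, opt_args),
    sampler = do.call(glucose_sampler, config$sampler),
    pmf = do.call(pmf_distributions, config$pmf)
  )
}

resolve_training <- function(config) {
  do.call(training_config,
          modifyList(list(seed = config$seed), config$training))
}

# Polynomial rolling hash (mod a Mersenne prime); used only as a config
# fingerprint in manifests, not for security.
string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(config) {
  string_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

write_manifest <- function(config, files, path) {
  jsonlite::write_json(
    list(seed = config$seed, config_hash = config_hash(config),
         files = files),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Simulate disjoint train and test cohorts and write them as CSV
#'
#' Generates `n_train` training subjects and `n_test` test subjects from
#' disjoint person pools, draws one observation per subject, and writes
#' `train.csv`, `test.csv` and a `manifest.json` recording the seed and a
#' fingerprint of the configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the two tibbles and the file paths.
#' @export
run_simulate <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$output_dir, 2) != 0) {
    abort(paste0("Output directory is not writable: ", config$output_dir))
  }
  datasets <- purrr::map(
    setNames(c("train", "test"), c("train", "test")),
    function(role) {
      parts <- resolve_configs(config, role)
      n <- if (role == "train") config$n_train else config$n_test
      persons <- generate_population(
        n, parts$optical, parts$pmf,
        id_prefix = if (role == "train") "TR" else "TE"
      )
      make_dataset(persons, 1L, parts$sampler, parts$optical)
    }
  )
  paths <- list(
    train = file.path(config$output_dir, "train.csv"),
    test = file.path(config$output_dir, "test.csv"),
    manifest = file.path(config$output_dir, "manifest.json")
  )
  write_observations(datasets$train, paths$train)
  write_observations(datasets$test, paths$test)
  write_manifest(config, list(train = "train.csv", test = "test.csv"),
                 paths$manifest)
  invisible(list(train = datasets$train, test = datasets$test, paths = paths))
}

#' Train the network on a simulated or recorded cohort CSV
#'
#' Runs stratified k-fold cross-validation for the fold-level report, then
#' trains the final model on all rows. Writes `model.json` (serialized
#' network + scaling) and `cv_report.csv` (one row per fold plus the pooled
#' row).
#'
#' @param config A [run_config()].
#' @param train_csv Path to an observation CSV ([write_observations()]
#'   schema).
#' @return Invisibly, a list with the `fit`, the `cv` object and file
#'   paths.
#' @export
run_train <- function(config, train_csv) {
  records <- read_observations(train_csv)
  tcfg <- resolve_training(config)
  cv <- sdnn_kfold_cv(records, k = config$k_folds, config = tcfg,
                      threshold = config$threshold)
  fit <- sdnn_train(records, tcfg)
  model_path <- file.path(config$output_dir, "model.json")
  cv_path <- file.path(config$output_dir, "cv_report.csv")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_sdnn(fit, model_path)
  report <- bind_rows(
    tidy(cv),
    bind_cols(tibble(fold = NA_integer_, n_val = length(cv$assignments)),
              cv$pooled_metrics)
  )
  write.csv(report, cv_path, row.names = FALSE)
  invisible(list(fit = fit, cv = cv,
                 paths = list(model = model_path, cv_report = cv_path)))
}

#' Evaluate a trained model on a held-out cohort CSV
#'
#' Produces the full clinical report: confusion metrics at the diagnostic
#' threshold, ROC/AUC, Clarke Error Grid zone counts, Bland-Altman
#' agreement, and the ISO 15197 accuracy check. Writes `evaluation.csv`
#' (one row per metric) and `ceg_points.csv`.
#'
#' @param model_path Path to a [write_sdnn()] model file.
#' @param test_csv Path to an observation CSV.
#' @param config A [run_config()].
#' @return Invisibly, a list with all report objects and the metric tibble.
#' @export
run_evaluate <- function(model_path, test_csv, config = run_config()) {
  fit <- read_sdnn(model_path)
  records <- read_observations(test_csv)
  missing_cols <- setdiff(fit$features, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Model expects feature(s) absent from the data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  pred <- predict(fit, records)
  truth <- records$dm_label
  cm <- confusion_matrix(truth = truth,
                         predicted = classify_dm(pred, config$threshold))
  metrics <- confusion_metrics(cm)
  roc <- roc_curve(pred, truth)
  ceg <- ceg_report(records$glucose_ref, pred)
  ba <- bland_altman(records$glucose_ref, pred, mode = config$ba_mode)
  iso <- iso15197_check(records$glucose_ref, pred)

  summary_tbl <- bind_rows(
    tibble(metric = c("accuracy", "precision", "sensitivity", "specificity"),
           value = c(metrics$accuracy, metrics$precision,
                     metrics$sensitivity, metrics$specificity)),
    tibble(metric = "auc", value = roc$auc),
    tibble(metric = paste0("ceg_frac_", names(ceg$zone_fractions)),
           value = as.numeric(ceg$zone_fractions)),
    tibble(metric = c("ba_bias", "ba_loa_low", "ba_loa_high"),
           value = c(ba$bias, ba$loa_low, ba$loa_high)),
    tibble(metric = c("iso_frac_within", "iso_frac_zone_ab",
                      "iso_overall_pass"),
           value = c(iso$frac_within, iso$frac_zone_ab,
                     as.numeric(iso$overall_pass)))
  )
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  eval_path <- file.path(config$output_dir, "evaluation.csv")
  ceg_path <- file.path(config$output_dir, "ceg_points.csv")
  write.csv(summary_tbl, eval_path, row.names = FALSE)
  write_ceg(ceg, ceg_path)
  invisible(list(
    predicted = pred, confusion = cm, metrics = metrics, roc = roc,
    ceg = ceg, bland_altman = ba, iso = iso, summary = summary_tbl,
    paths = list(evaluation = eval_path, ceg_points = ceg_path)
  ))
}

#' Centered moving-average low-pass filter
#'
#' Window 1 is the identity; edges are averaged over the partial window.
#'
#' @param x Numeric series.
#' @param window Odd window length (samples).
#' @return Filtered series, same length.
#' @export
low_pass_filter <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("`window` must be odd and >= 1.")
  if (length(x) == 0L) abort("Series is empty.")
  if (window == 1L) return(x)
  half <- window %/% 2L
  vapply(seq_along(x), function(i) {
    mean(x[max(1L, i - half):min(length(x), i + half)])
  }, numeric(1))
}

#' Simulate a monitoring session and predict glucose in real time
#'
#' Generates a meal time series for one simulated person, runs the trained
#' model on each time point's mbNIR readouts plus the person's PMF, and
#' low-pass filters the predicted series with a centered moving average.
#' Writes `monitor.csv` with the true and predicted glucose.
#'
#' @param config A [run_config()].
#' @param model_path Path to a trained [write_sdnn()] model.
#' @param events Data frame with `time` (minutes) and `event_type` columns.
#' @param duration Session length (minutes).
#' @return Invisibly, the time-series tibble with columns `time_min,
#'   glucose, nir_1..3, predicted, predicted_filtered`.
#' @export
run_monitor <- function(config, model_path, events, duration = 240) {
  fit <- read_sdnn(model_path)
  parts <- resolve_configs(config, "test")
  person <- generate_population(1, parts$optical, parts$pmf, id_prefix = "MON")
  ts <- meal_timeseries(person, events, duration, parts$optical)
  if (nrow(ts) == 0L) abort("Monitoring series is empty.")
  feats <- bind_cols(
    ts[, c("nir_1", "nir_2", "nir_3")],
    person[rep(1L, nrow(ts)), pmf_fields()]
  )
  ts$predicted <- predict(fit, feats)
  ts$predicted_filtered <- low_pass_filter(ts$predicted, config$filter_window)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_timeseries(ts, file.path(config$output_dir, "monitor.csv"))
  invisible(ts)
}
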