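# Shared fixtures. Small cohorts and short trainings keep unit tests fast;
# the full-scale 401/234 experiment used by the acceptance tests is built
# once on demand and cached for the session.

tiny_config <- function(seed = 42, ...) {
  optical_config(seed = seed, ...)
}

tiny_cohort <- function(n = 12, seed = 42, ...) {
  generate_population(n, tiny_config(seed = seed, ...))
}

tiny_dataset <- function(n = 12, seed = 42, samples = 1, noise_sd = 0.005) {
  cfg <- tiny_config(seed = seed, noise_sd = noise_sd)
  make_dataset(generate_population(n, cfg), samples, glucose_sampler(), cfg)
}

quick_training <- function(seed = 1, epochs = 200, ...) {
  training_config(seed = seed, epochs = epochs,
                  early_stop_patience = epochs, ...)
}

# Full-scale cohort experiment shared by the acceptance tests: simulate the
# 401-subject training and 234-subject test cohorts, train the full 9-field
# network and the NIR-only ablation once.
.cohort_cache <- new.env(parent = emptyenv())

cohort_experiment <- function() {
  if (!is.null(.cohort_cache$result)) return(.cohort_cache$result)
  cfg <- run_config(seed = 20260930, output_dir = tempfile("cohort"))
  sim <- run_simulate(cfg)
  tcfg <- training_config(seed = cfg$seed)
  fit_full <- sdnn_train(sim$train, tcfg)
  fit_nir <- sdnn_train(sim$train, tcfg,
                        features = c("nir_1", "nir_2", "nir_3"))
  .cohort_cache$result <- list(
    train = sim$train, test = sim$test,
    fit_full = fit_full, fit_nir = fit_nir,
    pred_full = predict(fit_full, sim$test),
    pred_nir = predict(fit_nir, sim$test)
  )
  .cohort_cache$result
}
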