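#' Fasting glucose sampler for a mixed healthy/diabetic cohort
#'
#' Two-component mixture over the 60-400 mg/dL detection range: a healthy
#' component, normal around 95 mg/dL, and a diabetic component with a long
#' right tail, `126 + Gamma(shape, scale)`. The mixture weight is the
#' probability of drawing the diabetic component; with the defaults the
#' marginal probability of glucose >= 126 mg/dL is close to 104/401, the
#' prevalence of the training cohort this generator emulates.
#'
#' @param dm_weight Probability of the diabetic mixture component.
#' @param healthy_mean,healthy_sd Healthy component (mg/dL).
#' @param dm_shape,dm_scale Gamma tail of the diabetic component (mg/dL
#'   above the 126 threshold).
#' @param range Clipping range of the readout (mg/dL).
#'
#' @return An object of class `glucose_sampler`: call it as
#'   `sampler$draw(n)` inside a seeded context.
#' @export
#'
#' @examples
#' s <- glucose_sampler()
#' set.seed(1); summary(s$draw(1000))
glucose_sampler <- function(dm_weight = 104 / 401,
                            healthy_mean = 95, healthy_sd = 12,
                            dm_shape = 1.6, dm_scale = 45,
                            range = c(60, 400)) {
  if (dm_weight < 0 || dm_weight > 1) abort("`dm_weight` must lie in [0, 1].")
  if (healthy_sd <= 0 || dm_shape <= 0 || dm_scale <= 0) {
    abort("Sampler scale parameters must be positive.")
  }
  draw <- function(n) {
    is_dm <- rbinom(n, 1L, dm_weight) == 1L
    g <- numeric(n)
    g[!is_dm] <- rnorm(sum(!is_dm), healthy_mean, healthy_sd)
    g[is_dm] <- 126 + stats::rgamma(sum(is_dm), shape = dm_shape, scale = dm_scale)
    pmin(pmax(g, range[1]), range[2])
  }
  structure(
    list(draw = draw, dm_weight = dm_weight, range = range,
         healthy_mean = healthy_mean, healthy_sd = healthy_sd,
         dm_shape = dm_shape, dm_scale = dm_scale),
    class = "glucose_sampler"
  )
}

#' Simulate mbNIR observation records for a cohort
#'
#' For every person draws `samples_per_person` reference glucose values from
#' the sampler, computes the noiseless three-band transmittance through the
#' personalized Beer-Lambert model, multiplies each readout by log-normal
#' noise of scale `config$noise_sd`, clips to (0, 1], and labels diabetes as
#' `glucose_ref >= 126`. Byte-identical across runs for a fixed
#' `config$seed` (the dataset stream is offset from the population stream so
#' cohort and samples are independently reproducible).
#'
#' @param persons Tibble from [generate_population()]; must be non-empty.
#' @param samples_per_person Samples to draw per subject (>= 1).
#' @param sampler A [glucose_sampler()].
#' @param config The [optical_config()] used for `persons`.
#'
#' @return A tibble of observation records with columns `person_id`,
#'   `nir_1..nir_3`, the six PMF fields, `glucose_ref` (mg/dL) and
#'   `dm_label` (1 iff `glucose_ref >= 126`).
#' @export
#'
#' @examples
#' cfg <- optical_config(seed = 3)
#' ds <- make_dataset(generate_population(10, cfg), 2, glucose_sampler(), cfg)
#' nrow(ds)
make_dataset <- function(persons, samples_per_person = 1L,
                         sampler = glucose_sampler(),
                         config = optical_config()) {
  stopifnot(inherits(config, "optical_config"))
  if (!inherits(sampler, "glucose_sampler")) {
    abort("`sampler` must be created with glucose_sampler().")
  }
  if (nrow(persons) == 0L) abort("`persons` must contain at least one subject.")
  if (samples_per_person < 1L) abort("`samples_per_person` must be >= 1.")
  samples_per_person <- as.integer(samples_per_person)

  set.seed(config$seed + 1000003L)
  n <- nrow(persons) * samples_per_person
  idx <- rep(seq_len(nrow(persons)), each = samples_per_person)
  expanded <- persons[idx, , drop = FALSE]
  glucose <- sampler$draw(n)

  nir <- transmittance_all_bands(expanded, glucose, config)
  if (config$noise_sd > 0) {
    noise <- matrix(rlnorm(n * 3L, meanlog = 0, sdlog = config$noise_sd),
                    nrow = n)
    nir <- pmin(nir * noise, 1)
  }

  bind_cols(
    tibble(person_id = expanded$person_id),
    as_tibble(nir),
    expanded[, pmf_fields()],
    tibble(
      glucose_ref = glucose,
      dm_label = as.integer(glucose >= 126)
    )
  )
}

#' Write / read observation records as CSV
#'
#' Plain CSV with the canonical column order `person_id, nir_1, nir_2,
#' nir_3, gender, age, weight, height, bmi, blood_pressure, glucose_ref,
#' dm_label`.
#'
#' @param records Observation tibble from [make_dataset()].
#' @param path File path.
#' @return `write_observations()` returns `path` invisibly;
#'   `read_observations()` returns the records tibble.
#' @export
write_observations <- function(records, path) {
  cols <- c("person_id", model_fields(), "glucose_ref", "dm_label")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Records are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("person_id", model_fields(), "glucose_ref", "dm_label")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV at `", path, "` lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_tibble(df)
}
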