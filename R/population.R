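#' Marginal distributions of the personal medical features
#'
#' Describes the cohort marginals used by [generate_population()]: truncated
#' normals for age, weight, height and systolic blood pressure, and a
#' Bernoulli gender code. Defaults emulate a Southeast-Asian adult screening
#' cohort with median age close to 50 years.
#'
#' @param age_mean,age_sd,age_min,age_max Age marginal (years); truncation
#'   bounds default to the adult inclusion window 18-90.
#' @param gender_p Probability of gender code 1.
#' @param weight_mean,weight_sd,weight_min,weight_max Weight marginal (kg).
#' @param height_mean,height_sd,height_min,height_max Height marginal (cm).
#' @param bp_mean,bp_sd,bp_min,bp_max Systolic blood pressure (mmHg).
#'
#' @return An object of class `pmf_distributions` (a named list).
#' @export
#'
#' @examples
#' pmf_distributions(age_mean = 55)
pmf_distributions <- function(age_mean = 50, age_sd = 13,
                              age_min = 18, age_max = 90,
                              gender_p = 0.5,
                              weight_mean = 65, weight_sd = 12,
                              weight_min = 40, weight_max = 120,
                              height_mean = 162, height_sd = 9,
                              height_min = 140, height_max = 195,
                              bp_mean = 128, bp_sd = 18,
                              bp_min = 90, bp_max = 200) {
  marginals <- list(
    age = c(mean = age_mean, sd = age_sd, min = age_min, max = age_max),
    gender_p = gender_p,
    weight = c(mean = weight_mean, sd = weight_sd, min = weight_min, max = weight_max),
    height = c(mean = height_mean, sd = height_sd, min = height_min, max = height_max),
    blood_pressure = c(mean = bp_mean, sd = bp_sd, min = bp_min, max = bp_max)
  )
  for (nm in c("age", "weight", "height", "blood_pressure")) {
    s <- marginals[[nm]]
    if (s[["sd"]] <= 0 || s[["min"]] <= 0 || s[["min"]] >= s[["max"]]) {
      abort(paste0("Invalid bounds for `", nm, "`: need sd > 0 and 0 < min < max."))
    }
  }
  if (gender_p < 0 || gender_p > 1) abort("`gender_p` must lie in [0, 1].")
  structure(marginals, class = "pmf_distributions")
}

# Truncated-normal draw by rejection; fine for the mild truncations used here.
rtruncnorm <- function(n, mean, sd, min, max) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < min | out > max)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < min | out[bad] > max]
  }
  out
}

# Standardize the PMF block against the generator's own marginal
# parameters (not the realized sample), so the PMF -> latent map is a fixed
# population-level function of the raw features.
standardize_pmf <- function(persons, dist) {
  cbind(
    gender = (persons$gender - dist$gender_p) /
      sqrt(max(dist$gender_p * (1 - dist$gender_p), 0.25)),
    age = (persons$age - dist$age[["mean"]]) / dist$age[["sd"]],
    weight = (persons$weight - dist$weight[["mean"]]) / dist$weight[["sd"]],
    height = (persons$height - dist$height[["mean"]]) / dist$height[["sd"]],
    bmi = (persons$bmi - 24.8) / 4,
    blood_pressure = (persons$blood_pressure - dist$blood_pressure[["mean"]]) /
      dist$blood_pressure[["sd"]]
  )
}

#' Generate a cohort of person profiles
#'
#' Draws `n_persons` subjects from the PMF marginals, derives BMI as
#' weight / (height/100)^2, and attaches the latent optical parameters:
#' per-species aggregate attenuation terms
#' `latent_attenuation = pmf_coefficients %*% standardized(PMF) + perturbation`
#' clipped at zero, and a log-normal effective glucose beam path
#' `path_length_g` that grows with BMI. Deterministic given `config$seed`.
#'
#' @param n_persons Number of subjects (>= 1).
#' @param config An [optical_config()].
#' @param pmf_dist A [pmf_distributions()] object.
#' @param id_prefix Prefix for the opaque `person_id` values.
#'
#' @return A tibble with one row per person: `person_id`, the six PMF
#'   columns, `latent_1` ... `latent_k` (one per interfering species) and
#'   `path_length_g`.
#' @export
#'
#' @examples
#' cohort <- generate_population(5, optical_config(seed = 7))
#' cohort$bmi - cohort$weight / (cohort$height / 100)^2
generate_population <- function(n_persons,
                                config = optical_config(),
                                pmf_dist = pmf_distributions(),
                                id_prefix = "P") {
  stopifnot(inherits(config, "optical_config"))
  if (!inherits(pmf_dist, "pmf_distributions")) {
    abort("`pmf_dist` must be created with pmf_distributions().")
  }
  if (!is.numeric(n_persons) || n_persons < 1) abort("`n_persons` must be >= 1.")
  n_persons <- as.integer(n_persons)

  set.seed(config$seed)
  d <- pmf_dist
  persons <- tibble(
    person_id = sprintf("%s%04d", id_prefix, seq_len(n_persons)),
    gender = rbinom(n_persons, 1L, d$gender_p),
    age = round(rtruncnorm(n_persons, d$age[["mean"]], d$age[["sd"]],
                           d$age[["min"]], d$age[["max"]])),
    weight = round(rtruncnorm(n_persons, d$weight[["mean"]], d$weight[["sd"]],
                              d$weight[["min"]], d$weight[["max"]]), 1),
    height = round(rtruncnorm(n_persons, d$height[["mean"]], d$height[["sd"]],
                              d$height[["min"]], d$height[["max"]]), 1)
  )
  persons$bmi <- round(persons$weight / (persons$height / 100)^2, 2)
  persons$blood_pressure <- round(rtruncnorm(
    n_persons, d$blood_pressure[["mean"]], d$blood_pressure[["sd"]],
    d$blood_pressure[["min"]], d$blood_pressure[["max"]]
  ))

  z <- standardize_pmf(persons, d)                     # n x 6
  lat_mean <- z %*% t(config$pmf_coefficients)         # n x n_species
  lat_mean <- sweep(lat_mean, 2, config$latent_base, `+`)
  perturb <- matrix(
    rnorm(n_persons * config$n_species, 0, config$latent_perturb_sd),
    nrow = n_persons
  )
  latent <- pmax(lat_mean + perturb, 0)
  colnames(latent) <- paste0("latent_", seq_len(config$n_species))

  persons <- bind_cols(persons, as_tibble(latent))
  persons$path_length_g <- as.numeric(exp(
    config$path_length_bmi_coef * z[, "bmi"] +
      rnorm(n_persons, 0, config$path_length_sd)
  ))
  persons
}

# Extract the latent attenuation matrix (n x n_species) from a persons tibble.
latent_matrix <- function(persons, config) {
  cols <- paste0("latent_", seq_len(config$n_species))
  missing_cols <- setdiff(cols, names(persons))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing latent attenuation columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  as.matrix(persons[, cols, drop = FALSE])
}
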