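#' Optical model configuration for the mbNIR cohort simulator
#'
#' Bundles every parameter of the personalized Beer-Lambert forward model:
#' the three NIR bands, the per-band glucose attenuation cross-sections, the
#' relative cross-sections of the interfering species (tissue, bone,
#' water/fat aggregates), the scattering turning point, the linear map from
#' standardized personal medical features (PMF) to latent attenuation means,
#' and the readout noise scale.
#'
#' Transmittance at band \eqn{b} for person \eqn{k} follows
#' \deqn{T_b^k = \exp[-(\sigma_{g,b}\, l_g^k\, h(g/400) + \sum_i \sigma_{ig,b,i} N_i^k)]}
#' where \eqn{h} is a C1, strictly increasing optical-depth profile whose
#' slope drops smoothly from 1 to `slope_after` around the turning point
#' `turning_point` (scattering starts to dominate absorption at high
#' glucose), and \eqn{N_i^k \ge 0} are the per-person aggregate attenuation
#' terms of the interfering species.
#'
#' @param bands Data frame with columns `center_nm`, `low_nm`, `high_nm`;
#'   exactly three rows with centers 850, 950 and 1150 nm.
#' @param sigma_g Numeric vector, length 3: per-band glucose attenuation
#'   cross-section (dimensionless, > 0).
#' @param sigma_ig Numeric 3 x n_species matrix: per-band relative
#'   attenuation cross-sections of the interfering species.
#' @param turning_point Glucose concentration (mg/dL) above which the
#'   marginal attenuation per unit glucose falls off; must lie in (60, 400).
#' @param turnover_sharpness Width of the logistic slope blend, in units of
#'   glucose scaled by 400 (> 0). The default 0.06 corresponds to about
#'   24 mg/dL.
#' @param slope_after Relative optical-depth slope above the turning point,
#'   in (0, 1]; 1 disables the turnover.
#' @param pmf_coefficients n_species x 6 matrix mapping the standardized PMF
#'   vector (gender, age, weight, height, bmi, blood_pressure) to latent
#'   attenuation means.
#' @param latent_base Numeric vector, length n_species: baseline latent
#'   attenuation per species before the PMF shift.
#' @param latent_perturb_sd Standard deviation of the per-person latent
#'   perturbation (same units as `latent_base`).
#' @param path_length_bmi_coef Log-scale coefficient linking standardized
#'   BMI to the effective glucose beam path (thicker tissue, longer path).
#' @param path_length_sd Log-scale standard deviation of the residual
#'   person-to-person path-length variation.
#' @param noise_sd Scale of the multiplicative log-normal readout noise.
#' @param seed Integer seed recorded in the configuration; all generator
#'   functions draw their randomness from it.
#'
#' @return An object of class `optical_config` (a named list).
#' @export
#'
#' @examples
#' cfg <- optical_config(seed = 1)
#' cfg$turning_point
optical_config <- function(bands = default_bands(),
                           sigma_g = c(3.2, 4.5, 2.4),
                           sigma_ig = default_sigma_ig(),
                           turning_point = 220,
                           turnover_sharpness = 0.06,
                           slope_after = 0.3,
                           pmf_coefficients = default_pmf_coefficients(),
                           latent_base = c(1.2, 0.9, 1.05),
                           latent_perturb_sd = 0.01,
                           path_length_bmi_coef = 0.12,
                           path_length_sd = 0.01,
                           noise_sd = 0.005,
                           seed = 1L) {
  bands <- as.data.frame(bands)
  stopifnot(
    nrow(bands) == 3L,
    all(c("center_nm", "low_nm", "high_nm") %in% names(bands))
  )
  if (!identical(sort(bands$center_nm), c(850, 950, 1150))) {
    abort("`bands` must have exactly three rows centered at 850, 950 and 1150 nm.")
  }
  sigma_ig <- as.matrix(sigma_ig)
  pmf_coefficients <- as.matrix(pmf_coefficients)
  n_species <- ncol(sigma_ig)
  if (length(sigma_g) != 3L || any(!is.finite(sigma_g)) || any(sigma_g <= 0)) {
    abort("`sigma_g` must be 3 finite positive values (one per band).")
  }
  if (nrow(sigma_ig) != 3L || any(!is.finite(sigma_ig)) || any(sigma_ig < 0)) {
    abort("`sigma_ig` must be a finite non-negative 3 x n_species matrix.")
  }
  if (!is.finite(turning_point) || turning_point <= 60 || turning_point >= 400) {
    abort("`turning_point` must lie strictly inside (60, 400) mg/dL.")
  }
  if (turnover_sharpness <= 0 || slope_after <= 0 || slope_after > 1) {
    abort("`turnover_sharpness` must be > 0 and `slope_after` in (0, 1].")
  }
  if (nrow(pmf_coefficients) != n_species || ncol(pmf_coefficients) != 6L) {
    abort("`pmf_coefficients` must be an n_species x 6 matrix (PMF order: gender, age, weight, height, bmi, blood_pressure).")
  }
  if (length(latent_base) != n_species || any(latent_base < 0)) {
    abort("`latent_base` must be non-negative, one entry per species.")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(
      bands = bands,
      sigma_g = as.numeric(sigma_g),
      sigma_ig = sigma_ig,
      turning_point = turning_point,
      turnover_sharpness = turnover_sharpness,
      slope_after = slope_after,
      pmf_coefficients = pmf_coefficients,
      latent_base = as.numeric(latent_base),
      latent_perturb_sd = latent_perturb_sd,
      path_length_bmi_coef = path_length_bmi_coef,
      path_length_sd = path_length_sd,
      noise_sd = noise_sd,
      n_species = n_species,
      seed = as.integer(seed)
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat("  bands (nm):", paste(x$bands$center_nm, collapse = ", "), "\n")
  cat("  sigma_g:", paste(signif(x$sigma_g, 3), collapse = ", "), "\n")
  cat("  species:", x$n_species,
      "| turning point:", x$turning_point, "mg/dL",
      "| slope after:", x$slope_after, "\n")
  cat("  noise_sd:", x$noise_sd, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Default NIR band table
#'
#' Three photonic bands: 800-900 nm centered at 850 nm, 900-1000 nm centered
#' at 950 nm, and 1100-1200 nm centered at 1150 nm.
#'
#' @return A data frame with columns `center_nm`, `low_nm`, `high_nm`.
#' @export
default_bands <- function() {
  data.frame(
    center_nm = c(850, 950, 1150),
    low_nm = c(800, 900, 1100),
    high_nm = c(900, 1000, 1200)
  )
}

#' Default relative cross-sections of the interfering species
#'
#' Rows are bands (850/950/1150 nm), columns the three aggregate species
#' (tissue, bone, water/fat). Values are relative to the glucose
#' cross-section of the same band, and are sized so that the interfering
#' species dominate the optical depth: without knowing the person, the
#' glucose signal is heavily confounded — the regime in which adding PMF
#' to the NIR readouts is essential.
#'
#' @return A 3 x 3 numeric matrix.
#' @export
default_sigma_ig <- function() {
  m <- rbind(
    c(1.08, 0.48, 0.84),
    c(0.60, 0.96, 0.36),
    c(0.84, 0.60, 1.20)
  )
  dimnames(m) <- list(
    band = c("850", "950", "1150"),
    species = c("tissue", "bone", "waterfat")
  )
  m
}

#' Default PMF-to-latent-attenuation coefficient matrix
#'
#' Linear map from the standardized PMF vector (gender, age, weight, height,
#' bmi, blood_pressure) to the mean latent attenuation of each species.
#' Signs encode the intended anatomy: heavier and higher-BMI subjects carry
#' more tissue and water/fat attenuation; height (longer finger bones) loads
#' on the bone term; age mildly increases all terms. Magnitudes are sized so
#' person-to-person interference at fixed glucose is comparable to the
#' glucose-induced transmittance change over the measuring range — the
#' premise that makes NIR alone ambiguous across persons and PMF
#' informative.
#'
#' @return A 3 x 6 numeric matrix.
#' @export
default_pmf_coefficients <- function() {
  m <- rbind(
    c(0.24, 0.18, 0.60, -0.12, 0.48, 0.12),
    c(0.36, 0.12, 0.12, 0.54, -0.18, 0.06),
    c(-0.12, 0.18, 0.42, -0.18, 0.60, 0.18)
  )
  dimnames(m) <- list(
    species = c("tissue", "bone", "waterfat"),
    pmf = c("gender", "age", "weight", "height", "bmi", "blood_pressure")
  )
  m
}

# Names of the 6 PMF fields in canonical order.
pmf_fields <- function() {
  c("gender", "age", "weight", "height", "bmi", "blood_pressure")
}

# Names of the 9 model-input fields in canonical order.
model_fields <- function() {
  c("nir_1", "nir_2", "nir_3", pmf_fields())
}
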