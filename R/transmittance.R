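#' Glucose optical-depth profile with a scattering turning point
#'
#' Strictly increasing C-infinity profile \eqn{h(u)} of scaled glucose
#' \eqn{u = g/400}. Its slope blends smoothly (logistic, width
#' `sharpness`) from 1 below the turning point to `slope_after` above it:
#' at low concentration absorbance grows linearly with glucose
#' (Beer-Lambert), while above the turning point scattering starts to
#' dominate and the marginal attenuation per unit glucose falls off.
#' Closed form:
#' \deqn{h(u) = u + (s-1)\, w\, [\log(1+e^{(u-u^*)/w}) - \log(1+e^{-u^*/w})]}
#' so that \eqn{h(0) = 0} and \eqn{h'(u) = 1 + (s-1)\,\mathrm{logistic}((u-u^*)/w)}.
#'
#' @param u Scaled glucose, `glucose / 400` (non-negative).
#' @param turning_point_u Turning point on the scaled axis (`g* / 400`).
#' @param sharpness Logistic blend width on the scaled axis (> 0).
#' @param slope_after Slope above the turning point, in (0, 1].
#'
#' @return `h(u)`, same length as `u`; zero at zero, strictly increasing.
#' @export
#'
#' @examples
#' glucose_depth_profile(c(0, 0.25, 0.5, 1), 0.55, 0.06, 0.3)
glucose_depth_profile <- function(u, turning_point_u, sharpness, slope_after) {
  # log1p(exp(x)) computed stably for large x
  softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  u + (slope_after - 1) * sharpness *
    (softplus((u - turning_point_u) / sharpness) -
       softplus(-turning_point_u / sharpness))
}

#' Beer-Lambert transmittance of one NIR band
#'
#' Forward optical model: for each person the detector readout at band
#' \eqn{b} is
#' \deqn{T = \exp[-(\sigma_{g,b}\, l_g\, h(g/400) + \sum_i \sigma_{ig,b,i} N_i)]}
#' with \eqn{h} the turning-point optical-depth profile
#' ([glucose_depth_profile()]), \eqn{l_g} the person's effective glucose
#' beam path and \eqn{N_i} the latent attenuation of interfering species
#' \eqn{i}. The result is noiseless transmittance in (0, 1]; readout noise
#' is added by [make_dataset()].
#'
#' Vectorized over persons and glucose: `persons` may have one row (recycled
#' over `glucose`) or as many rows as `glucose` has elements.
#'
#' @param persons Tibble of person profiles from [generate_population()].
#' @param glucose Blood glucose in mg/dL (>= 0).
#' @param band_index Band number 1..3 (850, 950, 1150 nm).
#' @param config The [optical_config()] used to generate `persons`.
#'
#' @return Numeric vector of transmittance values in (0, 1].
#' @export
#'
#' @examples
#' cfg <- optical_config(seed = 2)
#' p <- generate_population(1, cfg)
#' transmittance(p, c(80, 120, 200), 1, cfg)
transmittance <- function(persons, glucose, band_index, config) {
  stopifnot(inherits(config, "optical_config"))
  band_index <- as.integer(band_index)
  if (length(band_index) != 1L || band_index < 1L || band_index > 3L) {
    abort("`band_index` must be a single integer in 1..3.")
  }
  if (any(!is.finite(glucose)) || any(glucose < 0)) {
    abort("`glucose` must be finite and >= 0 (mg/dL).")
  }
  if (any(!is.finite(config$sigma_g)) || any(!is.finite(config$sigma_ig))) {
    abort("Optical configuration contains non-finite cross-sections.")
  }
  n <- max(nrow(persons), length(glucose))
  if (nrow(persons) != 1L && nrow(persons) != n) {
    abort("`persons` must have one row or one row per glucose value.")
  }
  lat <- latent_matrix(persons, config)
  lg <- persons$path_length_g
  if (nrow(persons) == 1L && length(glucose) > 1L) {
    lat <- lat[rep(1L, n), , drop = FALSE]
    lg <- rep(lg, n)
  }
  u <- rep(glucose, length.out = n) / 400
  h <- glucose_depth_profile(u, config$turning_point / 400,
                             config$turnover_sharpness, config$slope_after)
  tau_g <- config$sigma_g[band_index] * lg * h
  tau_i <- as.numeric(lat %*% config$sigma_ig[band_index, ])
  unname(exp(-(tau_g + tau_i)))
}

# All three bands at once: returns an n x 3 matrix (nir_1..nir_3).
transmittance_all_bands <- function(persons, glucose, config) {
  out <- vapply(
    1:3,
    function(b) transmittance(persons, glucose, b, config),
    numeric(max(nrow(persons), length(glucose)))
  )
  colnames(out) <- paste0("nir_", 1:3)
  out
}
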