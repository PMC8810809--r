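test_that("transmittance is exp(-optical depth): closed-form anchors", {
  # no attenuation at all -> T = 1
  cfg0 <- optical_config(
    pmf_coefficients = matrix(0, 3, 6), latent_base = c(0, 0, 0),
    latent_perturb_sd = 0, path_length_sd = 0, path_length_bmi_coef = 0,
    seed = 5
  )
  p0 <- generate_population(1, cfg0)
  expect_equal(transmittance(p0, 0, 1, cfg0), 1)

  # a single interfering species with total optical depth ln 2 -> T = 1/2
  sig <- matrix(0, 3, 3)
  sig[1, 1] <- log(2)
  cfg1 <- optical_config(
    sigma_ig = sig,
    pmf_coefficients = matrix(0, 3, 6), latent_base = c(1, 0, 0),
    latent_perturb_sd = 0, path_length_sd = 0, path_length_bmi_coef = 0,
    seed = 5
  )
  p1 <- generate_population(1, cfg1)
  expect_equal(transmittance(p1, 0, 1, cfg1), 0.5, tolerance = 1e-12)
})

test_that("readouts stay in (0, 1] and fall with each latent attenuation term", {
  cfg <- tiny_config(seed = 8)
  p <- tiny_cohort(n = 5, seed = 8)
  g <- c(60, 150, 250, 400)
  for (b in 1:3) {
    tt <- transmittance(p[rep(1, 4), ], g, b, cfg)
    expect_true(all(tt > 0 & tt <= 1))
  }
  # pairwise perturbation: bump one species -> transmittance cannot rise
  for (k in 1:3) {
    bumped <- p
    bumped[[paste0("latent_", k)]] <- bumped[[paste0("latent_", k)]] + 0.3
    for (b in 1:3) {
      expect_true(all(transmittance(bumped, 120, b, cfg) <=
                        transmittance(p, 120, b, cfg)))
    }
  }
})

test_that("transmittance decreases in glucose and flattens past the turning point", {
  cfg <- tiny_config(seed = 9)
  p <- tiny_cohort(n = 1, seed = 9)
  grid <- seq(60, 400, by = 2)
  tt <- transmittance(p[rep(1, length(grid)), ], grid, 2, cfg)
  expect_true(all(diff(tt) < 0))
  # |dT/dg| by finite differences: mean slope magnitude well below the
  # turning point vs well above it
  slope <- abs(diff(tt)) / 2
  below <- grid[-1] < cfg$turning_point - 40
  above <- grid[-1] > cfg$turning_point + 40
  expect_gt(mean(slope[below]), mean(slope[above]))
  # the depth profile itself is C1: numerical derivative of h is continuous
  u <- seq(0, 1, by = 1e-3)
  h <- glucose_depth_profile(u, cfg$turning_point / 400,
                             cfg$turnover_sharpness, cfg$slope_after)
  dh <- diff(h) / 1e-3
  expect_lt(max(abs(diff(dh))), 0.01)
  expect_equal(h[1], 0)
})

test_that("persons with different PMF trace different NIR-vs-glucose curves", {
  cfg <- optical_config(latent_perturb_sd = 0, path_length_sd = 0, seed = 10)
  cohort <- generate_population(6, cfg)
  g <- seq(80, 300, by = 20)
  curves <- vapply(
    seq_len(6),
    function(i) transmittance(cohort[rep(i, length(g)), ], g, 1, cfg),
    numeric(length(g))
  )
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gt(max(abs(curves[, i] - curves[, j])), 1e-6)
  }
})

test_that("invalid glucose or band index is rejected", {
  cfg <- tiny_config()
  p <- tiny_cohort(n = 1)
  expect_error(transmittance(p, -5, 1, cfg), "glucose")
  expect_error(transmittance(p, 100, 4, cfg), "band_index")
  expect_error(transmittance(p, Inf, 1, cfg), "glucose")
})
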