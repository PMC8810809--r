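test_that("records carry the 9 model fields with valid ranges and labels", {
  ds <- tiny_dataset(n = 60, seed = 13)
  expect_true(all(c("nir_1", "nir_2", "nir_3", "gender", "age", "weight",
                    "height", "bmi", "blood_pressure") %in% names(ds)))
  nir <- as.matrix(ds[, c("nir_1", "nir_2", "nir_3")])
  expect_true(all(nir > 0 & nir <= 1))
  expect_true(all(ds$glucose_ref >= 60 & ds$glucose_ref <= 400))
  expect_identical(ds$dm_label, as.integer(ds$glucose_ref >= 126))
})

test_that("noiseless records equal the exact transmittance values", {
  cfg <- tiny_config(seed = 21, noise_sd = 0)
  persons <- generate_population(8, cfg)
  ds <- make_dataset(persons, 1, glucose_sampler(), cfg)
  for (b in 1:3) {
    expect_equal(ds[[paste0("nir_", b)]],
                 transmittance(persons, ds$glucose_ref, b, cfg))
  }
})

test_that("dataset regeneration under the same seed is identical", {
  a <- tiny_dataset(n = 30, seed = 5)
  b <- tiny_dataset(n = 30, seed = 5)
  expect_identical(a, b)
  # and CSV round-trip preserves content to full printed precision
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(a, path)
  back <- read_observations(path)
  expect_equal(back$glucose_ref, a$glucose_ref, tolerance = 1e-12)
  expect_identical(back$dm_label, a$dm_label)
})

test_that("diabetic prevalence matches the sampler's threshold mass", {
  # the cohort the generator emulates has 104/401 subjects at or above the
  # 126 mg/dL diagnostic threshold; the positive count must fall inside the
  # binomial 95% band around that rate
  ds <- make_dataset(generate_population(401, optical_config(seed = 31)),
                     1, glucose_sampler(), optical_config(seed = 31))
  p <- 104 / 401
  band <- qbinom(c(0.025, 0.975), 401, p)
  expect_gte(sum(ds$dm_label), band[1])
  expect_lte(sum(ds$dm_label), band[2])
})

test_that("larger-sample label prevalence concentrates on the sampler mass", {
  s <- glucose_sampler()
  set.seed(77)
  g <- s$draw(20000)
  prev <- mean(g >= 126)
  expect_lt(abs(prev - 104 / 401), 0.02)
})

test_that("degenerate inputs are rejected", {
  cfg <- tiny_config()
  expect_error(make_dataset(generate_population(3, cfg)[0, ], 1,
                            glucose_sampler(), cfg), "at least one")
  expect_error(make_dataset(generate_population(3, cfg), 0,
                            glucose_sampler(), cfg), "samples_per_person")
})
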