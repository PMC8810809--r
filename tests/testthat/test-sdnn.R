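make_params <- function(sizes, fill = 0, output = "regression") {
  p <- list()
  for (l in 1:3) {
    p[[paste0("W", l)]] <- matrix(fill, sizes[l], sizes[l + 1])
    p[[paste0("b", l)]] <- rep(0, sizes[l + 1])
  }
  p$layer_sizes <- sizes
  p$output <- output
  class(p) <- "sdnn_params"
  p
}

test_that("forward pass closed-form anchors hold", {
  sizes <- c(9L, 50L, 30L, 1L)
  x <- matrix(rnorm(9), 1, 9)

  # all-zero network: hidden activations are sigmoid(0) = 0.5, output
  # rectifier(0) = 0
  p0 <- make_params(sizes)
  fw <- sdnn_forward(x, p0, keep_activations = TRUE)
  expect_equal(unname(fw$out), 0)
  expect_true(all(fw$H1 == 0.5) && all(fw$H2 == 0.5))

  # negative output bias is clamped by the rectifier
  pneg <- make_params(sizes)
  pneg$b3 <- -1
  expect_equal(unname(sdnn_forward(x, pneg)), 0)

  # hand-computed 2-2-1 network with integer weights
  ph <- make_params(c(2L, 2L, 2L, 1L))
  ph$W1 <- matrix(c(1, -1, 2, 0), 2, 2)
  ph$b1 <- c(0.5, -0.5)
  ph$W2 <- matrix(c(1, 1, -2, 1), 2, 2)
  ph$b2 <- c(0, 1)
  ph$W3 <- matrix(c(3, -1), 2, 1)
  ph$b3 <- 0.25
  xin <- matrix(c(1, 2), 1, 2)
  s <- function(z) 1 / (1 + exp(-z))
  h1 <- s(c(1 * 1 + 2 * (-1) + 0.5, 1 * 2 + 2 * 0 - 0.5))
  h2 <- s(c(h1[1] * 1 + h1[2] * 1 + 0, h1[1] * (-2) + h1[2] * 1 + 1))
  expected <- max(h2[1] * 3 + h2[2] * (-1) + 0.25, 0)
  expect_equal(unname(sdnn_forward(xin, ph)), expected, tolerance = 1e-12)
})

test_that("forward output is non-negative and hidden activations lie in (0,1)", {
  set.seed(1)
  for (i in 1:10) {
    p <- sdnn_init(9, training_config(seed = i))
    X <- matrix(rnorm(9 * 20, sd = 3), 20, 9)
    fw <- sdnn_forward(X, p, keep_activations = TRUE)
    expect_true(all(fw$out >= 0))
    expect_true(all(fw$H1 > 0 & fw$H1 < 1))
    expect_true(all(fw$H2 > 0 & fw$H2 < 1))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(11)
  for (case in 1:5) {
    n_in <- sample(2:5, 1)
    cfg <- training_config(seed = case, hidden_sizes = c(4L, 3L))
    p <- sdnn_init(n_in, cfg)
    X <- matrix(rnorm(n_in * 7), 7, n_in)
    y <- runif(7, 0, 1)
    g <- sdnn_gradient(p, X, y)
    eps <- 1e-6
    for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
      idx <- seq_along(p[[nm]])
      if (length(idx) > 4) idx <- sample(idx, 4)
      for (i in idx) {
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
        fd <- (nirglucose:::sdnn_loss(pp, X, y) -
                 nirglucose:::sdnn_loss(pm, X, y)) / (2 * eps)
        denom <- max(abs(fd), abs(g[[nm]][i]), 1e-8)
        expect_lt(abs(fd - g[[nm]][i]) / denom, 1e-5)
      }
    }
  }
})

test_that("training fits a single person's noiseless curve (convergence smoke)", {
  cfg <- tiny_config(seed = 23, noise_sd = 0)
  persons <- generate_population(1, cfg)
  ds <- make_dataset(persons, 120, glucose_sampler(), cfg)
  # constant PMF columns (one person) legitimately trigger the
  # zero-variance scaling warning tested elsewhere
  fit <- suppressWarnings(
    sdnn_train(ds, quick_training(seed = 2, epochs = 2000))
  )
  h <- fit$history
  expect_identical(h$epoch[1], 0)
  expect_lt(h$train_loss[nrow(h)], 0.01 * h$train_loss[1])
})

test_that("training is deterministic under a fixed seed", {
  ds <- tiny_dataset(n = 25, seed = 3)
  f1 <- sdnn_train(ds, quick_training(seed = 7, epochs = 50))
  f2 <- sdnn_train(ds, quick_training(seed = 7, epochs = 50))
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, ds), predict(f2, ds))
})

test_that("zero-variance features are scaled with sd = 1 and a warning", {
  ds <- tiny_dataset(n = 20, seed = 4)
  ds$gender <- 1L
  expect_warning(
    fit <- sdnn_train(ds, quick_training(seed = 1, epochs = 5)),
    "Zero-variance"
  )
  expect_equal(unname(fit$scaling$scale[["gender"]]), 1)
})

test_that("diabetes thresholding is inclusive at 126 mg/dL", {
  expect_identical(classify_dm(c(125.9, 126, 400)), c(0L, 1L, 1L))
  expect_error(classify_dm(-1), ">= 0")
})

test_that("a serialized model reloads to matching predictions", {
  ds <- tiny_dataset(n = 30, seed = 6)
  fit <- sdnn_train(ds, quick_training(seed = 5, epochs = 40))
  path <- withr::local_tempfile(fileext = ".json")
  write_sdnn(fit, path)
  back <- read_sdnn(path)
  expect_identical(back$features, fit$features)
  expect_identical(back$input_link, fit$input_link)
  expect_equal(predict(back, ds), predict(fit, ds), tolerance = 1e-12)
})

test_that("shape mismatches are rejected", {
  p <- make_params(c(9L, 50L, 30L, 1L))
  expect_error(sdnn_forward(matrix(0, 2, 5), p), "width")
})
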