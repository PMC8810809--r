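#' Training configuration for the shallow dense network
#'
#' Hyperparameters of the 9-50-30-1 glucose regressor. Training is plain
#' mini-batch gradient descent on the mean-squared error of glucose scaled
#' by `target_scaling` (the 400 mg/dL upper detection limit), with feature
#' standardization fit on the training split only and early stopping on a
#' held-out validation fraction. NIR intensity channels enter the network
#' on the absorbance axis (`-log` of the readout) before standardization:
#' under Beer-Lambert attenuation the glucose information is linear in
#' absorbance but exponentially compressed in raw intensity, which
#' conditions the regression badly at high glucose.
#'
#' @param learning_rate Gradient-descent step size (> 0).
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size (>= 1).
#' @param seed Integer seed; initialization, shuffling and the validation
#'   split all draw from it.
#' @param init_scale Half-width of the uniform weight initialization.
#' @param target_scaling Glucose divisor mapping mg/dL to the unit scale the
#'   loss is computed on (> 0).
#' @param early_stop_patience Epochs without smoothed-validation improvement
#'   before stopping; `Inf` (the default) disables early stopping, because
#'   the small validation split monitors too noisily to be trusted to halt
#'   a run that is still fitting.
#' @param val_fraction Fraction of the training data held out for early
#'   stopping (0 disables the split and early stopping).
#' @param hidden_sizes Sizes of the two sigmoid hidden layers.
#' @param output `"regression"` (rectified linear output predicting scaled
#'   glucose, the default) or `"binary"` (sigmoid output trained on the
#'   diabetes label).
#' @param input_link `"absorbance"` (default: NIR channels enter as
#'   `-log` intensity) or `"identity"` (all features raw).
#'
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.1, epochs = 20000L,
                            batch_size = 64L, seed = 1L, init_scale = 0.5,
                            target_scaling = 400,
                            early_stop_patience = Inf,
                            val_fraction = 0.1,
                            hidden_sizes = c(50L, 30L),
                            output = c("regression", "binary"),
                            input_link = c("absorbance", "identity")) {
  output <- match.arg(output)
  input_link <- match.arg(input_link)
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  if (batch_size < 1) abort("`batch_size` must be >= 1.")
  if (target_scaling <= 0) abort("`target_scaling` must be > 0.")
  if (init_scale <= 0) abort("`init_scale` must be > 0.")
  if (val_fraction < 0 || val_fraction >= 1) abort("`val_fraction` must be in [0, 1).")
  structure(
    list(
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), seed = as.integer(seed),
      init_scale = init_scale, target_scaling = target_scaling,
      early_stop_patience = as.numeric(early_stop_patience),
      val_fraction = val_fraction,
      hidden_sizes = as.integer(hidden_sizes), output = output,
      input_link = input_link
    ),
    class = "training_config"
  )
}

# Map NIR intensity columns to the absorbance axis (-log T); other feature
# columns pass through unchanged. Intensities are floored at a tiny
# positive value so a zero readout cannot produce an infinite absorbance.
apply_input_link <- function(X, link) {
  if (identical(link, "identity")) return(X)
  nir_cols <- grepl("^nir_", colnames(X))
  X[, nir_cols] <- -log(pmax(X[, nir_cols, drop = FALSE], 1e-12))
  X
}

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

#' Initialize network parameters
#'
#' Weights drawn uniformly from `[-init_scale, init_scale]`, hidden biases
#' zero. The regression head's output bias is set so the pre-activation is
#' centered at mid target scale under the expected hidden activation 0.5,
#' keeping the rectified output unit active at initialization.
#' Layer sizes are `n_inputs` -> hidden sigmoid layers -> 1.
#'
#' @param n_inputs Number of input features (9 for the full mbNIR + PMF set).
#' @param config A [training_config()].
#' @return An object of class `sdnn_params`: weight matrices `W1..W3` and
#'   bias vectors `b1..b3`.
#' @export
sdnn_init <- function(n_inputs, config = training_config()) {
  sizes <- c(n_inputs, config$hidden_sizes, 1L)
  params <- list()
  for (l in 1:3) {
    params[[paste0("W", l)]] <- matrix(
      runif(sizes[l] * sizes[l + 1], -config$init_scale, config$init_scale),
      nrow = sizes[l]
    )
    params[[paste0("b", l)]] <- numeric(sizes[l + 1])
  }
  if (identical(config$output, "regression")) {
    # Center the output pre-activation near mid target scale under the
    # expected hidden activation 0.5, so the rectified unit starts active:
    # a dead output (all pre-activations negative) would never recover.
    params$b3 <- 0.5 - 0.5 * sum(params$W3)
  }
  params$layer_sizes <- sizes
  params$output <- config$output
  structure(params, class = "sdnn_params")
}

check_params <- function(params, X) {
  if (!inherits(params, "sdnn_params")) abort("`params` must be sdnn_params.")
  if (ncol(X) != nrow(params$W1)) {
    abort(sprintf("Feature width %d does not match network input width %d.",
                  ncol(X), nrow(params$W1)))
  }
  ok <- all(vapply(params[c("W1", "W2", "W3", "b1", "b2", "b3")],
                   function(p) all(is.finite(p)), logical(1)))
  if (!ok) abort("Network parameters contain non-finite values.")
}

#' Forward pass of the shallow dense network
#'
#' Computes `out = act(W3' s(W2' s(W1' x + b1) + b2) + b3)` for every row of
#' `X`, with `s` the logistic sigmoid on the two hidden layers and `act` the
#' rectifier (regression head) or sigmoid (binary head) on the output node.
#' The regression output is on the scaled-glucose axis, non-negative by
#' construction; multiply by `target_scaling` to get mg/dL (done by
#' [predict.sdnn_fit()]).
#'
#' @param X Numeric matrix, one row per sample, of standardized features.
#' @param params An [sdnn_init()] parameter set.
#' @param keep_activations Return hidden activations alongside the output
#'   (used by backpropagation).
#' @return Numeric vector of outputs, or a list with activations if
#'   `keep_activations = TRUE`.
#' @export
sdnn_forward <- function(X, params, keep_activations = FALSE) {
  X <- as.matrix(X)
  check_params(params, X)
  if (any(!is.finite(X))) abort("`X` must be finite.")
  Z1 <- sweep(X %*% params$W1, 2, params$b1, `+`)
  H1 <- sigmoid(Z1)
  Z2 <- sweep(H1 %*% params$W2, 2, params$b2, `+`)
  H2 <- sigmoid(Z2)
  z3 <- as.numeric(H2 %*% params$W3) + params$b3
  out <- if (identical(params$output, "binary")) sigmoid(z3) else relu(z3)
  if (keep_activations) list(out = out, z3 = z3, H2 = H2, H1 = H1, X = X) else out
}

# Mean-squared-error loss on the network's own output scale.
sdnn_loss <- function(params, X, y) {
  mean((sdnn_forward(X, params) - y)^2)
}

#' Backpropagation gradient of the mean-squared-error loss
#'
#' Analytic gradient of `mean((forward(X) - y)^2)` with respect to every
#' weight matrix and bias vector. The rectifier subgradient at zero is taken
#' as zero; the binary head differentiates through the output sigmoid.
#'
#' @param params An `sdnn_params` object.
#' @param X Feature matrix (rows = samples).
#' @param y Target vector on the network output scale.
#' @return A list `W1, b1, W2, b2, W3, b3` of gradients with the shapes of
#'   the corresponding parameters.
#' @export
sdnn_gradient <- function(params, X, y) {
  fw <- sdnn_forward(X, params, keep_activations = TRUE)
  n <- length(y)
  d_out <- 2 * (fw$out - y) / n
  d_z3 <- if (identical(params$output, "binary")) {
    d_out * fw$out * (1 - fw$out)
  } else {
    d_out * as.numeric(fw$z3 > 0)
  }
  gW3 <- crossprod(fw$H2, d_z3)          # 30 x 1
  gb3 <- sum(d_z3)
  d_H2 <- tcrossprod(d_z3, as.numeric(params$W3))  # n x 30
  d_Z2 <- d_H2 * fw$H2 * (1 - fw$H2)
  gW2 <- crossprod(fw$H1, d_Z2)
  gb2 <- colSums(d_Z2)
  d_H1 <- d_Z2 %*% t(params$W2)
  d_Z1 <- d_H1 * fw$H1 * (1 - fw$H1)
  gW1 <- crossprod(fw$X, d_Z1)
  gb1 <- colSums(d_Z1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

# Fit per-feature mean/sd on a training block; zero-variance features get
# sd = 1 with a warning rather than failing.
fit_feature_scaling <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  degenerate <- !is.finite(scale) | scale == 0
  if (any(degenerate)) {
    warn(paste0("Zero-variance feature(s) scaled with sd = 1: ",
                paste(colnames(X)[degenerate], collapse = ", ")))
    scale[degenerate] <- 1
  }
  list(center = center, scale = scale)
}

apply_feature_scaling <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$center, `-`), 2, scaling$scale, `/`)
}

# Extract the model feature matrix from an observation tibble.
feature_matrix <- function(records, features = model_fields()) {
  missing_cols <- setdiff(features, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Records are missing model fields: ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(records[, features, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Train the shallow dense glucose network
#'
#' Standardizes the selected feature columns (mean/sd fit on the training
#' rows only), scales reference glucose by `target_scaling`, and runs
#' mini-batch gradient descent on the MSE with uniform random weight
#' initialization. A `val_fraction` split is held out and its smoothed loss
#' stops training once it stops improving for `early_stop_patience` epochs;
#' the final parameters are kept. Deterministic given `config$seed`.
#'
#' @param records Observation tibble (see [make_dataset()]) with the feature
#'   columns, `glucose_ref` and `dm_label`.
#' @param config A [training_config()].
#' @param features Character vector of feature columns; defaults to the 9
#'   canonical mbNIR + PMF fields.
#'
#' @return An object of class `sdnn_fit`: trained `params`, the feature
#'   `scaling`, `features`, `target_scaling`, and a per-epoch `history`
#'   tibble of training/validation loss.
#' @export
#'
#' @examples
#' cfg <- optical_config(seed = 5)
#' ds <- make_dataset(generate_population(40, cfg), 1, glucose_sampler(), cfg)
#' fit <- sdnn_train(ds, training_config(epochs = 30, seed = 5))
#' glance(fit)
sdnn_train <- function(records, config = training_config(),
                       features = model_fields()) {
  stopifnot(inherits(config, "training_config"))
  if (nrow(records) == 0L) abort("Training data is empty.")
  X_raw <- apply_input_link(feature_matrix(records, features),
                            config$input_link)
  if (any(!is.finite(X_raw))) abort("Training features must be finite.")
  y <- if (identical(config$output, "binary")) {
    as.numeric(records$dm_label)
  } else {
    records$glucose_ref / config$target_scaling
  }

  # One full training run from a given seed. A rectified output unit whose
  # pre-activation goes negative for every sample is "dead": its gradient
  # is identically zero and training can never recover, so such runs are
  # detected and restarted from a shifted initialization seed.
  run_attempt <- function(seed) {
    set.seed(seed)
    n <- nrow(X_raw)
    n_val <- floor(config$val_fraction * n)
    val_idx <- if (n_val >= 1) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)

    scaling <- fit_feature_scaling(X_raw[tr_idx, , drop = FALSE])
    X <- apply_feature_scaling(X_raw, scaling)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

    params <- sdnn_init(ncol(X), config)
    best <- params
    best_val <- Inf
    stall <- 0L
    lr <- config$learning_rate
    history <- vector("list", config$epochs + 1L)
    history[[1L]] <- c(
      epoch = 0,
      train_loss = sdnn_loss(params, Xtr, ytr),
      val_loss = if (n_val >= 1) sdnn_loss(params, Xval, yval) else NA_real_
    )
    dead <- FALSE
    # The validation split is small, so a single epoch's validation loss is
    # a noisy monitor; smooth it over a trailing window before comparing.
    smooth_window <- 100L
    val_trace <- rep(NA_real_, config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(tr_idx))
      starts <- seq(1, length(ord), by = config$batch_size)
      for (s in starts) {
        b <- ord[s:min(s + config$batch_size - 1L, length(ord))]
        g <- sdnn_gradient(params, Xtr[b, , drop = FALSE], ytr[b])
        for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
          params[[nm]] <- params[[nm]] - lr * g[[nm]]
        }
      }
      out_tr <- sdnn_forward(Xtr, params)
      train_loss <- mean((out_tr - ytr)^2)
      val_loss <- if (n_val >= 1) sdnn_loss(params, Xval, yval) else NA_real_
      history[[epoch + 1L]] <- c(epoch = epoch, train_loss = train_loss,
                                 val_loss = val_loss)
      if (identical(config$output, "regression") && all(out_tr == 0) &&
          any(ytr > 0)) {
        dead <- TRUE
        break
      }
      monitor <- if (n_val >= 1) {
        val_trace[epoch] <- val_loss
        mean(val_trace[max(1L, epoch - smooth_window + 1L):epoch])
      } else {
        train_loss
      }
      if (monitor < best_val - 1e-12) {
        best_val <- monitor
        best <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (n_val >= 1 && stall >= config$early_stop_patience) break
      }
    }

    history <- as_tibble(
      do.call(rbind, history[!vapply(history, is.null, logical(1))])
    )
    # The smoothed validation loss only decides when to stop; the final
    # parameters are returned. The validation split is too small to rank
    # parameter snapshots reliably, and fixed-step gradient descent on this
    # population-sized network does not overfit within the epoch budget.
    list(best = params, best_val = best_val, scaling = scaling,
         history = history, n_tr = length(tr_idx), n_val = n_val,
         dead = dead)
  }

  max_restarts <- 5L
  for (attempt in seq_len(max_restarts)) {
    res <- run_attempt(config$seed + (attempt - 1L) * 500009L)
    if (!res$dead) break
  }
  if (res$dead) {
    warn("Output unit dead after all restarts; returning last attempt.")
  }
  best <- res$best
  scaling <- res$scaling
  history <- res$history
  structure(
    list(
      params = best, scaling = scaling, features = features,
      target_scaling = config$target_scaling, output = config$output,
      input_link = config$input_link,
      config = config, history = history, n_train = res$n_tr,
      n_val = res$n_val, best_loss = res$best_val,
      restarts = attempt - 1L
    ),
    class = "sdnn_fit"
  )
}

#' Predict glucose (or DM probability) for new records
#'
#' Applies the fit's stored feature scaling, runs the forward pass, and
#' de-scales the regression output back to mg/dL. The binary head returns
#' the sigmoid probability instead.
#'
#' @param object An [sdnn_train()] fit.
#' @param newdata Observation tibble with the fit's feature columns, or a
#'   numeric matrix already in feature order.
#' @param ... Unused.
#' @return Numeric vector: predicted glucose in mg/dL (regression head) or
#'   DM probability (binary head).
#' @export
predict.sdnn_fit <- function(object, newdata, ...) {
  X_raw <- if (is.matrix(newdata)) newdata else feature_matrix(newdata, object$features)
  X_raw <- apply_input_link(X_raw, object$input_link)
  X <- apply_feature_scaling(X_raw, object$scaling)
  out <- sdnn_forward(X, object$params)
  if (identical(object$output, "binary")) out else out * object$target_scaling
}

#' Threshold-based diabetes classification
#'
#' The fasting-glucose diagnostic rule: positive ("High") iff predicted
#' glucose is at or above the threshold, 126 mg/dL by default. The boundary
#' is inclusive, matching the "126 mg/dL or higher" criterion.
#'
#' @param predicted_glucose Predicted glucose in mg/dL (>= 0).
#' @param threshold Diagnostic threshold in mg/dL.
#' @return Integer vector of 0/1 labels.
#' @export
#'
#' @examples
#' classify_dm(c(125.9, 126, 400))
classify_dm <- function(predicted_glucose, threshold = 126) {
  if (any(predicted_glucose < 0, na.rm = TRUE)) {
    abort("`predicted_glucose` must be >= 0.")
  }
  as.integer(predicted_glucose >= threshold)
}

#' @export
print.sdnn_fit <- function(x, ...) {
  sizes <- x$params$layer_sizes
  cat("<sdnn_fit> ", paste(sizes, collapse = "-"),
      " (", x$output, " head)\n", sep = "")
  cat("  trained on", x$n_train, "samples (+", x$n_val, "validation),",
      max(x$history$epoch), "epochs\n")
  cat("  best monitored MSE:", signif(x$best_loss, 4), "\n")
  invisible(x)
}

#' @rdname sdnn_train
#' @param x,object An `sdnn_fit`.
#' @param ... Unused.
#' @method glance sdnn_fit
#' @export
glance.sdnn_fit <- function(x, ...) {
  tibble(
    n_train = x$n_train, n_val = x$n_val,
    epochs_run = max(x$history$epoch),
    train_mse = x$history$train_loss[nrow(x$history)],
    best_monitored_mse = x$best_loss,
    n_features = length(x$features),
    output = x$output
  )
}

#' @rdname sdnn_train
#' @method tidy sdnn_fit
#' @export
tidy.sdnn_fit <- function(x, ...) {
  p <- x$params
  purrr::map(1:3, function(l) {
    W <- p[[paste0("W", l)]]
    tibble(
      layer = l,
      term = c("weights", "bias"),
      n_parameters = c(length(W), length(p[[paste0("b", l)]])),
      mean_abs = c(mean(abs(W)), mean(abs(p[[paste0("b", l)]])))
    )
  }) |> list_rbind()
}

#' Serialize / restore a trained network as JSON
#'
#' Plain-text JSON holding layer sizes, row-major weight values, biases,
#' the feature names and scaling constants, and the target scaling, so a
#' fit can be reloaded and produce bit-identical predictions.
#'
#' @param fit An `sdnn_fit`.
#' @param path File path (`.json`).
#' @return `write_sdnn()` returns `path` invisibly; `read_sdnn()` the fit.
#' @export
write_sdnn <- function(fit, path) {
  stopifnot(inherits(fit, "sdnn_fit"))
  p <- fit$params
  payload <- list(
    layer_sizes = p$layer_sizes,
    output = fit$output,
    weights = purrr::map(1:3, ~ as.numeric(t(p[[paste0("W", .x)]]))),
    biases = purrr::map(1:3, ~ as.numeric(p[[paste0("b", .x)]])),
    features = fit$features,
    input_link = fit$input_link,
    scaling_center = as.numeric(fit$scaling$center),
    scaling_scale = as.numeric(fit$scaling$scale),
    target_scaling = fit$target_scaling
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sdnn
#' @export
read_sdnn <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(j$layer_sizes)
  params <- list(layer_sizes = sizes, output = j$output)
  for (l in 1:3) {
    params[[paste0("W", l)]] <- matrix(j$weights[[l]], nrow = sizes[l],
                                       byrow = TRUE)
    params[[paste0("b", l)]] <- as.numeric(j$biases[[l]])
  }
  class(params) <- "sdnn_params"
  structure(
    list(
      params = params,
      scaling = list(center = setNames(j$scaling_center, j$features),
                     scale = setNames(j$scaling_scale, j$features)),
      features = j$features, target_scaling = j$target_scaling,
      output = j$output,
      input_link = if (is.null(j$input_link)) "identity" else j$input_link,
      config = NULL,
      history = tibble(), n_train = NA_integer_, n_val = NA_integer_,
      best_loss = NA_real_
    ),
    class = "sdnn_fit"
  )
}
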