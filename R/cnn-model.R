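# model container, forward pass, training wrappers around the compiled core,
# and text-based serialization

# internal: map config strings to the integer codes the C++ core uses
activation_code <- function(activation) match(activation, c("relu", "sigmoid")) - 1L
loss_code <- function(loss) match(loss, c("cross_entropy", "mse")) - 1L

# internal: per-sample loss weights; with class balancing each class
# contributes half the batch loss regardless of fold imbalance
class_weights <- function(labels, balance) {
  n <- length(labels)
  if (!balance || length(unique(labels)) < 2) return(rep(1, n))
  n_by <- table(factor(labels, levels = c(0, 1)))
  as.numeric(n / (2 * n_by[as.character(labels)]))
}

# internal: output lengths of the conv and pool stages for input length N
cnn_dims <- function(config, n_input) {
  check_that(n_input >= config$kernel_len,
             "input length is shorter than the kernel")
  l_conv <- (n_input - config$kernel_len) %/% config$kernel_stride + 1L
  check_that(l_conv >= config$pool_len,
             "feature map is shorter than the pool window")
  p_pool <- (l_conv - config$pool_len) %/% config$pool_stride + 1L
  list(n_input = as.integer(n_input), l_conv = as.integer(l_conv),
       p_pool = as.integer(p_pool),
       d_flat = as.integer(p_pool * config$n_kernels))
}

#' Initialize an untrained CNN model
#'
#' Weights are drawn uniformly on `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`
#' (fan-in scaled), biases start at 0, and all draws are governed by
#' `config$init_seed`, so initialization is fully reproducible.
#'
#' @param config a [cnn_config()].
#' @param n_input input feature length N.
#' @param n_classes number of output classes (2 for a two-group study).
#' @return an object of class `cnn_model` with elements `kernels` (m x K),
#'   `dense_weights` (D x C), `dense_bias` (C), `config`, `dims`.
#' @export
init_cnn_model <- function(config, n_input, n_classes = 2) {
  stopifnot(inherits(config, "cnn_config"))
  dims <- cnn_dims(config, n_input)
  set.seed(config$init_seed)
  m <- config$kernel_len; k <- config$n_kernels; d <- dims$d_flat
  kernels <- matrix(stats::runif(m * k, -1 / sqrt(m), 1 / sqrt(m)), m, k)
  dense_w <- matrix(stats::runif(d * n_classes, -1 / sqrt(d), 1 / sqrt(d)),
                    d, n_classes)
  structure(
    list(kernels = kernels, dense_weights = dense_w,
         dense_bias = numeric(n_classes), config = config, dims = dims,
         loss_trace = NULL),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "cnn_model: %d kernels 1x%d -> conv %d -> pool %d -> dense %d x %d%s\n",
    x$config$n_kernels, x$config$kernel_len, x$dims$l_conv, x$dims$p_pool,
    nrow(x$dense_weights), ncol(x$dense_weights),
    if (is.null(x$loss_trace)) " (untrained)" else
      sprintf(" (trained %d epochs, final loss %.4g)",
              length(x$loss_trace), utils::tail(x$loss_trace, 1))))
  invisible(x)
}

#' Forward pass of the CNN
#'
#' Composes convolution, activation, max pooling, flattening (kernel-major),
#' the dense layer and softmax, returning the class probabilities together
#' with every intermediate needed for interpretation.
#'
#' @param model a `cnn_model`.
#' @param x numeric vector (a [feature_series()]'s values) of the model's
#'   input length.
#' @return list with `probs` (length C, sums to 1), `conv` (L x K
#'   pre-activations), `activated` (L x K), `pooled` (P x K), `flat`
#'   (length D) and `logits` (length C).
#' @export
cnn_forward <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  if (inherits(x, "feature_series")) x <- x$values
  check_that(length(x) == model$dims$n_input,
             sprintf("input length %d does not match model input length %d",
                     length(x), model$dims$n_input))
  cfg <- model$config
  u <- conv1d(x, model$kernels, stride = cfg$kernel_stride)
  y <- activate(u, cfg$activation)
  pooled <- max_pool1d(y, cfg$pool_len, cfg$pool_stride)
  flat <- as.vector(pooled) # column-major: kernel-major blocks of length P
  logits <- dense_forward(flat, model$dense_weights, model$dense_bias)
  list(probs = softmax(logits), conv = u, activated = y, pooled = pooled,
       flat = flat, logits = logits)
}

#' Classification loss
#'
#' Cross-entropy `-log p[label]` (default) or squared error against the
#' one-hot target. The log argument is clamped away from 0.
#'
#' @param probs probability vector from [softmax()].
#' @param label true class in `0..C-1`.
#' @param loss `"cross_entropy"` or `"mse"`.
#' @return non-negative scalar; 0 iff the true class has probability 1.
#' @export
cnn_loss <- function(probs, label, loss = c("cross_entropy", "mse")) {
  loss <- match.arg(loss)
  check_that(label %in% (seq_along(probs) - 1), "'label' out of range")
  if (loss == "cross_entropy") {
    -log(max(probs[label + 1], 1e-12))
  } else {
    target <- as.numeric(seq_along(probs) - 1 == label)
    sum((probs - target)^2)
  }
}

#' Backpropagation gradients of the mean loss over a dataset
#'
#' Analytic gradients of the mean training loss with respect to every model
#' parameter, computed by the compiled core. Used by [cnn_train()] and
#' directly testable against finite differences.
#'
#' @param model a `cnn_model`.
#' @param x numeric matrix, subjects x N.
#' @param labels integer vector of 0/1 labels.
#' @param weights optional per-sample loss weights; by default derived from
#'   the model config's `balance_classes` setting.
#' @return list with `loss` (weighted mean over rows), `probs` (n x C),
#'   `kernel_grad` (m x K), `dense_grad` (D x C), `bias_grad` (C).
#' @export
cnn_gradients <- function(model, x, labels, weights = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  x <- as.matrix(x)
  check_that(ncol(x) == model$dims$n_input, "feature length mismatch")
  check_that(nrow(x) == length(labels), "one label per row required")
  cfg <- model$config
  if (is.null(weights)) weights <- class_weights(labels, cfg$balance_classes)
  check_that(length(weights) == nrow(x), "one weight per row required")
  cnn_grad_cpp(x, as.integer(labels), as.numeric(weights), model$kernels,
               model$dense_weights, model$dense_bias, cfg$kernel_stride,
               cfg$pool_len, cfg$pool_stride,
               activation_code(cfg$activation), loss_code(cfg$loss))
}

#' Train the CNN with momentum SGD
#'
#' Runs `config$epochs` passes of momentum SGD
#' (`v <- momentum * v - lr * grad; w <- w + v`) from a seeded random
#' initialization. In the default full-batch mode the gradient is the mean
#' over all subjects, so the step size does not depend on cohort size.
#' Training is deterministic given `init_seed` and the data order.
#'
#' @param x numeric matrix, subjects x N, or a list of [feature_series()].
#' @param labels integer vector of 0/1 labels (taken from the series when
#'   `x` is a list).
#' @param config a [cnn_config()].
#' @return a trained `cnn_model` with a per-epoch `loss_trace`.
#' @export
cnn_train <- function(x, labels = NULL, config = cnn_config()) {
  if (is.list(x) && !is.matrix(x) && all(vapply(x, inherits, logical(1),
                                                "feature_series"))) {
    if (is.null(labels)) labels <- vapply(x, function(f) f$label, integer(1))
    x <- do.call(rbind, lapply(x, function(f) f$values))
  }
  x <- as.matrix(x)
  check_that(!is.null(labels) && length(labels) == nrow(x),
             "one label per training row is required")
  labels <- as.integer(labels)
  check_that(all(labels %in% c(0L, 1L)), "labels must be 0 or 1")
  check_that(length(unique(labels)) == 2,
             "training data must contain both classes")
  stopifnot(inherits(config, "cnn_config"))

  model <- init_cnn_model(config, n_input = ncol(x))
  cfg <- config
  weights <- class_weights(labels, cfg$balance_classes)
  fit <- cnn_train_cpp(x, labels, weights, model$kernels, model$dense_weights,
                       model$dense_bias, cfg$kernel_stride, cfg$pool_len,
                       cfg$pool_stride, activation_code(cfg$activation),
                       loss_code(cfg$loss), cfg$learning_rate, cfg$momentum,
                       cfg$epochs,
                       match(cfg$batch_mode, c("full", "sample")) - 1L,
                       match(cfg$momentum_form, c("plain", "ema")) - 1L)
  model$kernels <- fit$kernels
  model$dense_weights <- fit$dense_weights
  model$dense_bias <- as.numeric(fit$dense_bias)
  model$loss_trace <- as.numeric(fit$loss_trace)
  model
}

#' Predict the class of a feature series
#'
#' Argmax over the softmax probabilities; an exact tie resolves to class 0.
#'
#' @param model a trained `cnn_model`.
#' @param x numeric vector or [feature_series()].
#' @return list with `label` (0 or 1) and `probs`.
#' @export
cnn_predict <- function(model, x) {
  probs <- cnn_forward(model, x)$probs
  # which.max takes the first maximum, so a 0.5/0.5 tie yields class 0
  list(label = which.max(probs) - 1L, probs = probs)
}

#' Serialize a CNN model to a self-describing text file
#'
#' JSON with the configuration in plain fields and the weights as base64 of
#' their IEEE-754 doubles, so a round trip restores them bit-exactly.
#'
#' @param model a `cnn_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cnn_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  enc <- function(x) jsonlite::base64_enc(writeBin(as.vector(x), raw(),
                                                   size = 8, endian = "little"))
  obj <- list(
    format = "nirscnn-model-1",
    config = unclass(model$config),
    dims = model$dims,
    n_classes = ncol(model$dense_weights),
    kernels_b64 = enc(model$kernels),
    dense_weights_b64 = enc(model$dense_weights),
    dense_bias_b64 = enc(model$dense_bias),
    loss_trace_b64 = if (is.null(model$loss_trace)) NULL else
      enc(model$loss_trace))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a CNN model written by [write_cnn_model()]
#' @param path model file.
#' @return a `cnn_model`.
#' @export
read_cnn_model <- function(path) {
  obj <- jsonlite::read_json(path)
  check_that(identical(obj$format, "nirscnn-model-1"),
             "not a recognized model file")
  dec <- function(b64) readBin(jsonlite::base64_dec(b64), "double",
                               n = 1e7, size = 8, endian = "little")
  config <- do.call(cnn_config, as_plain_list(obj$config))
  m <- config$kernel_len; k <- config$n_kernels
  dims <- lapply(obj$dims, as.integer)
  n_classes <- as.integer(obj$n_classes)
  model <- structure(
    list(kernels = matrix(dec(obj$kernels_b64), m, k),
         dense_weights = matrix(dec(obj$dense_weights_b64), dims$d_flat,
                                n_classes),
         dense_bias = dec(obj$dense_bias_b64),
         config = config, dims = dims,
         loss_trace = if (is.character(obj$loss_trace_b64) &&
                            nzchar(obj$loss_trace_b64))
           dec(obj$loss_trace_b64) else NULL),
    class = "cnn_model")
  model
}
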