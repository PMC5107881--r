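#' CNN hyperparameter configuration
#'
#' Defaults follow the reference two-class fNIRS classifier: learning rate
#' 0.05, momentum 0.998, nine 1 x 10 kernels slid with stride 1, 1 x 2 max
#' pooling, 5000 epochs of momentum SGD. Pooling is non-overlapping by
#' default (`pool_stride = pool_len = 2`) so a 200-element input's feature
#' maps are halved, and the stride is exposed for other designs.
#'
#' @param learning_rate SGD step size.
#' @param momentum momentum coefficient of the velocity update
#'   `v <- momentum * v - learning_rate * grad; w <- w + v`.
#' @param kernel_len kernel length m (1 x m kernels).
#' @param kernel_stride convolution stride in samples.
#' @param pool_len max-pooling window length.
#' @param pool_stride pooling stride; default equals `pool_len`
#'   (non-overlapping).
#' @param n_kernels number of kernels K.
#' @param epochs training epochs.
#' @param activation `"relu"` (default) or `"sigmoid"`.
#' @param loss `"cross_entropy"` (default) or `"mse"` against one-hot labels.
#' @param batch_mode `"full"` (one mean-gradient update per epoch, default)
#'   or `"sample"` (per-sample updates in data order).
#' @param balance_classes weight each subject's loss inversely to its class
#'   frequency (default `TRUE`). Leave-one-out folds are intrinsically
#'   imbalanced by one subject; without balancing the classifier learns the
#'   fold's majority class, which in leave-one-out is always the wrong answer
#'   for the held-out subject and biases null channels below chance.
#' @param momentum_form `"plain"` heavy-ball (`v <- momentum*v - lr*grad;
#'   w <- w + v`) or the momentum-corrected `"ema"` form
#'   (`v <- momentum*v + (1-momentum)*grad; w <- w - lr*v`), whose effective
#'   step does not grow with `1/(1-momentum)`.
#' @param init_seed seed for the random weight initialization.
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(learning_rate = 0.05, momentum = 0.998,
                       kernel_len = 10, kernel_stride = 1, pool_len = 2,
                       pool_stride = pool_len, n_kernels = 9, epochs = 5000,
                       activation = c("relu", "sigmoid"),
                       loss = c("cross_entropy", "mse"),
                       batch_mode = c("full", "sample"),
                       balance_classes = TRUE,
                       momentum_form = c("plain", "ema"), init_seed = 1L) {
  check_scalar(learning_rate, "learning_rate", nonneg = TRUE)
  check_scalar(momentum, "momentum", nonneg = TRUE)
  check_scalar(kernel_len, "kernel_len", positive = TRUE, integerish = TRUE)
  check_scalar(kernel_stride, "kernel_stride", positive = TRUE, integerish = TRUE)
  check_scalar(pool_len, "pool_len", positive = TRUE, integerish = TRUE)
  check_scalar(pool_stride, "pool_stride", positive = TRUE, integerish = TRUE)
  check_scalar(n_kernels, "n_kernels", positive = TRUE, integerish = TRUE)
  check_scalar(epochs, "epochs", positive = TRUE, integerish = TRUE)
  check_scalar(init_seed, "init_seed", integerish = TRUE)
  check_that(isTRUE(balance_classes) || isFALSE(balance_classes),
             "'balance_classes' must be TRUE or FALSE")
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         kernel_len = as.integer(kernel_len),
         kernel_stride = as.integer(kernel_stride),
         pool_len = as.integer(pool_len),
         pool_stride = as.integer(pool_stride),
         n_kernels = as.integer(n_kernels), epochs = as.integer(epochs),
         activation = match.arg(activation), loss = match.arg(loss),
         batch_mode = match.arg(batch_mode),
         balance_classes = balance_classes,
         momentum_form = match.arg(momentum_form),
         init_seed = as.integer(init_seed)),
    class = "cnn_config"
  )
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf(
    "cnn_config: K=%d kernels 1x%d (stride %d), pool 1x%d (stride %d)\n",
    x$n_kernels, x$kernel_len, x$kernel_stride, x$pool_len, x$pool_stride))
  cat(sprintf("  lr %g, momentum %g, %d epochs, %s activation, %s loss, %s batch\n",
              x$learning_rate, x$momentum, x$epochs, x$activation, x$loss,
              x$batch_mode))
  invisible(x)
}

#' Valid 1D convolution of a feature vector with a bank of kernels
#'
#' `u[i, k] = sum_a x[(i-1)*stride + a] * kernels[a, k]` with no padding:
#' the output has `(N - m) / stride + 1` rows, one column per kernel.
#'
#' @param x numeric vector of length N.
#' @param kernels m x K numeric matrix, one kernel per column.
#' @param stride convolution stride.
#' @return L x K matrix of feature maps.
#' @export
conv1d <- function(x, kernels, stride = 1) {
  kernels <- as.matrix(kernels)
  n <- length(x); m <- nrow(kernels)
  check_that(n >= m, "input is shorter than the kernel")
  check_scalar(stride, "stride", positive = TRUE, integerish = TRUE)
  l_out <- (n - m) %/% stride + 1
  patches <- matrix(0, l_out, m)
  for (a in seq_len(m)) {
    patches[, a] <- x[(seq_len(l_out) - 1) * stride + a]
  }
  patches %*% kernels
}

#' Elementwise activation
#'
#' @param u numeric vector or matrix of pre-activations.
#' @param activation `"relu"` or `"sigmoid"`.
#' @return same shape as `u`.
#' @export
activate <- function(u, activation = c("relu", "sigmoid")) {
  activation <- match.arg(activation)
  if (activation == "relu") pmax(u, 0) else 1 / (1 + exp(-u))
}

#' 1D max pooling
#'
#' Each output element is the maximum over a window of `pool_len` inputs;
#' windows advance by `pool_stride`. With non-overlapping width-2 pooling an
#' even-length input is halved (200 elements pool to 100).
#'
#' @param y numeric vector or L x K matrix (pooled per column).
#' @param pool_len pooling window length.
#' @param pool_stride pooling stride.
#' @return pooled vector or matrix with `floor((L - pool_len) / pool_stride) + 1`
#'   rows.
#' @export
max_pool1d <- function(y, pool_len = 2, pool_stride = pool_len) {
  check_scalar(pool_len, "pool_len", positive = TRUE, integerish = TRUE)
  check_scalar(pool_stride, "pool_stride", positive = TRUE, integerish = TRUE)
  if (is.matrix(y)) {
    out <- apply(y, 2, max_pool1d, pool_len = pool_len,
                 pool_stride = pool_stride)
    if (!is.matrix(out)) out <- matrix(out, nrow = 1) # single pooled position
    return(out)
  }
  l_in <- length(y)
  check_that(l_in >= pool_len, "input is shorter than the pool window")
  p_out <- (l_in - pool_len) %/% pool_stride + 1
  starts <- (seq_len(p_out) - 1) * pool_stride
  vapply(starts, function(s) max(y[s + seq_len(pool_len)]), numeric(1))
}

#' Fully connected (dense) layer
#'
#' `u[j] = sum_i pooled[i] * weights[i, j] + bias[j]` mapping the flattened
#' pooled activations to one pre-activation per class.
#'
#' @param pooled numeric vector of length D (flattened pooled activations,
#'   kernel-major).
#' @param weights D x C numeric matrix.
#' @param bias length-C numeric vector.
#' @return length-C numeric vector of class pre-activations.
#' @export
dense_forward <- function(pooled, weights, bias) {
  weights <- as.matrix(weights)
  check_that(length(pooled) == nrow(weights),
             "pooled length does not match dense weight rows")
  check_that(length(bias) == ncol(weights),
             "bias length does not match dense weight columns")
  as.numeric(crossprod(weights, pooled) + bias)
}

#' Overflow-safe softmax
#'
#' `p[j] = exp(u[j]) / sum_k exp(u[k])`, computed after subtracting
#' `max(u)` (softmax is shift-invariant) so arbitrarily large inputs do not
#' overflow.
#'
#' @param u numeric vector of pre-activations.
#' @return probability vector of the same length: positive, sums to 1.
#' @export
softmax <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}
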