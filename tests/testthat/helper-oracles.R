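# naive scalar-loop reference implementations of every layer, kept free of
# vectorized shortcuts so they can arbitrate the production code

oracle_conv <- function(x, kernels, stride = 1) {
  kernels <- as.matrix(kernels)
  m <- nrow(kernels); k <- ncol(kernels)
  l_out <- (length(x) - m) %/% stride + 1
  u <- matrix(0, l_out, k)
  for (kk in seq_len(k)) {
    for (i in seq_len(l_out)) {
      acc <- 0
      for (a in seq_len(m)) acc <- acc + x[(i - 1) * stride + a] * kernels[a, kk]
      u[i, kk] <- acc
    }
  }
  u
}

oracle_activate <- function(u, activation = "relu") {
  out <- u
  for (i in seq_along(u)) {
    out[i] <- if (activation == "relu") max(u[i], 0) else 1 / (1 + exp(-u[i]))
  }
  out
}

oracle_pool <- function(y, pool_len, pool_stride) {
  l_in <- length(y)
  p_out <- (l_in - pool_len) %/% pool_stride + 1
  out <- numeric(p_out)
  for (c in seq_len(p_out)) {
    best <- -Inf
    for (a in seq_len(pool_len)) {
      v <- y[(c - 1) * pool_stride + a]
      if (v > best) best <- v
    }
    out[c] <- best
  }
  out
}

oracle_dense <- function(pooled, weights, bias) {
  c_out <- ncol(weights)
  u <- numeric(c_out)
  for (j in seq_len(c_out)) {
    acc <- bias[j]
    for (i in seq_len(nrow(weights))) acc <- acc + weights[i, j] * pooled[i]
    u[j] <- acc
  }
  u
}

oracle_softmax <- function(u) {
  e <- numeric(length(u))
  for (j in seq_along(u)) e[j] <- exp(u[j] - max(u))
  e / sum(e)
}

# full scalar-loop forward pass mirroring the model composition
oracle_forward <- function(model, x) {
  cfg <- model$config
  u <- oracle_conv(x, model$kernels, cfg$kernel_stride)
  y <- apply(u, 2, oracle_activate, activation = cfg$activation)
  pooled <- apply(y, 2, oracle_pool, pool_len = cfg$pool_len,
                  pool_stride = cfg$pool_stride)
  if (!is.matrix(pooled)) pooled <- matrix(pooled, nrow = 1)
  flat <- numeric(0)
  for (k in seq_len(ncol(pooled))) flat <- c(flat, pooled[, k])
  logits <- oracle_dense(flat, model$dense_weights, model$dense_bias)
  oracle_softmax(logits)
}

# random small model + input for oracle-equivalence sweeps
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(8:20, 1)
  m <- sample(2:min(5, n), 1)
  k <- sample(1:3, 1)
  stride <- sample(1:2, 1)
  l_conv <- (n - m) %/% stride + 1
  pool_len <- sample(1:min(2, l_conv), 1)
  cfg <- cnn_config(kernel_len = m, kernel_stride = stride,
                    pool_len = pool_len, pool_stride = pool_len,
                    n_kernels = k, epochs = 5,
                    activation = sample(c("relu", "sigmoid"), 1),
                    init_seed = seed)
  model <- init_cnn_model(cfg, n)
  list(model = model, x = stats::runif(n, -1, 2), n = n)
}

# separable toy dataset: every feature equals the label plus small noise
toy_separable <- function(n = 10, n_feat = 20, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rep(labels, n_feat), n, n_feat) +
    matrix(stats::runif(n * n_feat, -0.1, 0.1), n, n_feat)
  list(x = x, labels = labels)
}

# small, fast cohorts for pipeline-level tests
small_sim_config <- function(n_per_group = 4, n_channels = 3, ...) {
  simulation_config(n_per_group = n_per_group, n_channels = n_channels, ...)
}

fast_cnn_config <- function(...) {
  cnn_config(epochs = 100, ...)
}
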