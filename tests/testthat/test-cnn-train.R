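test_that("loss matches its definition and is monotone in the true-class probability", {
  expect_equal(cnn_loss(c(1, 0), 0), 0, tolerance = 1e-9)
  expect_equal(cnn_loss(c(0.5, 0.5), 1), -log(0.5))
  expect_lt(cnn_loss(c(0.8, 0.2), 0), cnn_loss(c(0.6, 0.4), 0))
  expect_equal(cnn_loss(c(0.5, 0.5), 0, loss = "mse"), 0.5)
  expect_error(cnn_loss(c(0.5, 0.5), 2), "range")
})

test_that("zero learning rate leaves the initialization untouched", {
  toy <- toy_separable(6, 15, seed = 3)
  cfg <- cnn_config(learning_rate = 0, kernel_len = 4, n_kernels = 2,
                    epochs = 20, init_seed = 5)
  fit <- cnn_train(toy$x, toy$labels, cfg)
  init <- init_cnn_model(cfg, 15)
  expect_identical(fit$kernels, init$kernels)
  expect_identical(fit$dense_weights, init$dense_weights)
  expect_identical(fit$dense_bias, init$dense_bias)
})

test_that("backprop matches central finite differences on a tiny instance", {
  set.seed(12)
  cfg <- cnn_config(kernel_len = 3, n_kernels = 2, init_seed = 4)
  model <- init_cnn_model(cfg, 12)
  x <- matrix(stats::runif(4 * 12), 4, 12)
  labels <- c(0L, 1L, 1L, 0L)
  w <- nirscnn:::class_weights(labels, TRUE)
  g <- cnn_gradients(model, x, labels)
  batch_loss <- function(m) {
    mean(w * vapply(1:4, function(s)
      cnn_loss(cnn_forward(m, x[s, ])$probs, labels[s]), numeric(1)))
  }
  expect_equal(g$loss, batch_loss(model), tolerance = 1e-12)
  h <- 1e-5
  grads <- list(kernels = g$kernel_grad, dense_weights = g$dense_grad,
                dense_bias = as.numeric(g$bias_grad))
  for (fld in names(grads)) {
    for (i in seq_along(model[[fld]])) {
      mp <- model; mp[[fld]][i] <- mp[[fld]][i] + h
      mm <- model; mm[[fld]][i] <- mm[[fld]][i] - h
      fd <- (batch_loss(mp) - batch_loss(mm)) / (2 * h)
      expect_equal(grads[[fld]][i], fd, tolerance = 1e-5)
    }
  }
})

test_that("training separates a linearly separable toy set quickly", {
  toy <- toy_separable(10, 20, seed = 1)
  cfg <- cnn_config(kernel_len = 5, n_kernels = 3, epochs = 500, init_seed = 3)
  fit <- cnn_train(toy$x, toy$labels, cfg)
  pred <- vapply(seq_len(10), function(s) cnn_predict(fit, toy$x[s, ])$label,
                 integer(1))
  expect_equal(mean(pred == toy$labels), 1)
  expect_lt(utils::tail(fit$loss_trace, 1), fit$loss_trace[1])
})

test_that("training is deterministic and rejects single-class data", {
  toy <- toy_separable(6, 15, seed = 2)
  cfg <- cnn_config(kernel_len = 4, n_kernels = 2, epochs = 50, init_seed = 11)
  a <- cnn_train(toy$x, toy$labels, cfg)
  b <- cnn_train(toy$x, toy$labels, cfg)
  expect_identical(a$kernels, b$kernels)
  expect_identical(a$loss_trace, b$loss_trace)
  expect_identical(cnn_predict(a, toy$x[1, ]), cnn_predict(b, toy$x[1, ]))
  expect_error(cnn_train(toy$x, rep(0L, 6), cfg), "both classes")
})

test_that("alternative training modes run and stay deterministic", {
  toy <- toy_separable(6, 15, seed = 5)
  for (args in list(list(batch_mode = "sample"),
                    list(momentum_form = "ema"),
                    list(loss = "mse"),
                    list(activation = "sigmoid"),
                    list(balance_classes = FALSE))) {
    cfg <- do.call(cnn_config, c(list(kernel_len = 4, n_kernels = 2,
                                      epochs = 40, init_seed = 6), args))
    a <- cnn_train(toy$x, toy$labels, cfg)
    b <- cnn_train(toy$x, toy$labels, cfg)
    expect_identical(a$kernels, b$kernels)
    expect_true(all(is.finite(a$loss_trace)))
  }
})

test_that("ties in the output probabilities resolve to class 0", {
  cfg <- cnn_config(kernel_len = 3, n_kernels = 2, epochs = 10, init_seed = 2)
  model <- init_cnn_model(cfg, 12)
  model$dense_weights[] <- 0
  model$dense_bias[] <- 0
  out <- cnn_predict(model, stats::runif(12))
  expect_equal(out$probs, c(0.5, 0.5))
  expect_identical(out$label, 0L)
})

test_that("model serialization round-trips bit-exactly", {
  toy <- toy_separable(6, 15, seed = 7)
  cfg <- cnn_config(kernel_len = 4, n_kernels = 2, epochs = 30, init_seed = 9)
  fit <- cnn_train(toy$x, toy$labels, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_cnn_model(fit, path)
  back <- read_cnn_model(path)
  expect_identical(back$kernels, fit$kernels)
  expect_identical(back$dense_weights, fit$dense_weights)
  expect_identical(back$dense_bias, fit$dense_bias)
  expect_identical(back$loss_trace, fit$loss_trace)
  expect_equal(back$config, fit$config)
  x <- stats::runif(15)
  expect_identical(cnn_forward(back, x)$probs, cnn_forward(fit, x)$probs)
})
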