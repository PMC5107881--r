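# small trained model + features shared across interpretation tests
interp_fixture <- function() {
  toy <- toy_separable(8, 30, seed = 13)
  cfg <- cnn_config(kernel_len = 4, n_kernels = 3, epochs = 150, init_seed = 21)
  list(model = cnn_train(toy$x, toy$labels, cfg), x = toy$x,
       labels = toy$labels)
}

test_that("kernel export returns the model's kernels in index order", {
  cfg <- cnn_config(init_seed = 31) # reference defaults: nine 1 x 10 kernels
  model <- init_cnn_model(cfg, 200)
  prof <- export_kernels(model)
  expect_equal(dim(prof), c(10, 9))
  expect_equal(unname(prof), model$kernels)
  # untrained model exports its seeded initialization, and the export
  # survives serialization unchanged
  path <- withr::local_tempfile(fileext = ".json")
  write_cnn_model(model, path)
  expect_equal(export_kernels(read_cnn_model(path)), prof)
})

test_that("pooled outputs are class means of per-subject pooled activations", {
  fx <- interp_fixture()
  po <- pooled_outputs(fx$model, fx$x, fx$labels)
  expect_equal(dim(po), c(fx$model$dims$p_pool, 3, 2))
  # independent composition: pool(activate(convolve(x))) averaged per class
  for (cl in 0:1) {
    members <- which(fx$labels == cl)
    manual <- Reduce(`+`, lapply(members, function(s) {
      y <- activate(conv1d(fx$x[s, ], fx$model$kernels), "relu")
      max_pool1d(y, 2, 2)
    })) / length(members)
    expect_equal(po[, , cl + 1], manual, ignore_attr = TRUE, tolerance = 1e-12)
  }
  # one subject per class: the means are those subjects' activations verbatim
  po1 <- pooled_outputs(fx$model, fx$x[c(1, 5), ], fx$labels[c(1, 5)])
  expect_equal(po1[, , 1],
               cnn_forward(fx$model, fx$x[1, ])$pooled, ignore_attr = TRUE)
  expect_error(pooled_outputs(fx$model, fx$x[1:4, ], rep(0L, 4)), "both classes")
})

test_that("dense-weighted pooled outputs equal the elementwise product", {
  fx <- interp_fixture()
  p <- fx$model$dims$p_pool
  for (ki in 1:3) {
    wp <- weighted_pooled_output(fx$model, fx$x, fx$labels, ki, 1)
    po <- pooled_outputs(fx$model, fx$x, fx$labels)
    w <- fx$model$dense_weights[(ki - 1) * p + seq_len(p), 2]
    manual0 <- vapply(seq_len(p), function(i) po[i, ki, 1] * w[i], numeric(1))
    expect_equal(unname(wp[, 1]), manual0, tolerance = 1e-12)
  }
  # identity and zero weightings
  m1 <- fx$model
  m1$dense_weights[] <- 1
  wp1 <- weighted_pooled_output(m1, fx$x, fx$labels, 2, 0)
  po <- pooled_outputs(m1, fx$x, fx$labels)
  expect_equal(unname(wp1[, 2]), unname(po[, 2, 2]))
  m0 <- fx$model
  m0$dense_weights[] <- 0
  expect_true(all(weighted_pooled_output(m0, fx$x, fx$labels, 1, 1) == 0))
  # linearity in the dense weights
  m2 <- fx$model
  m2$dense_weights <- 2 * m2$dense_weights
  expect_equal(weighted_pooled_output(m2, fx$x, fx$labels, 3, 1),
               2 * weighted_pooled_output(fx$model, fx$x, fx$labels, 3, 1))
  expect_error(weighted_pooled_output(fx$model, fx$x, fx$labels, 9, 1),
               "range")
})

test_that("the most discriminative kernel is found by the separation score", {
  fx <- interp_fixture()
  # constructed model: only kernel 2's dense weights are nonzero, so only
  # kernel 2 can carry any class difference
  m <- fx$model
  p <- m$dims$p_pool
  m$dense_weights[] <- 0
  m$dense_weights[(2 - 1) * p + seq_len(p), 2] <- 1
  best <- most_discriminative_kernel(m, fx$x, fx$labels)
  expect_equal(best$kernel, 2L)
  expect_true(all(best$scores[c(1, 3)] == 0))
  # identical class means give zero scores everywhere and index 1 by tie-break
  x_same <- rbind(fx$x[1:2, ], fx$x[1:2, ])
  same <- most_discriminative_kernel(fx$model, x_same, c(0L, 0L, 1L, 1L))
  expect_equal(same$kernel, 1L)
  expect_equal(max(abs(same$scores)), 0)
  # symmetric under class relabeling
  sw <- most_discriminative_kernel(fx$model, fx$x, 1L - fx$labels)
  expect_equal(sw$scores, most_discriminative_kernel(fx$model, fx$x,
                                                     fx$labels)$scores)
})

test_that("interpretation bundles assemble and export as delimited text", {
  fx <- interp_fixture()
  bundle <- interpretation_bundle(fx$model, fx$x, fx$labels)
  expect_s3_class(bundle, "interpretation_bundle")
  expect_equal(bundle$kernel_profiles, export_kernels(fx$model))
  expect_equal(dim(bundle$inputs_by_class), c(30, 2))
  dir <- withr::local_tempdir()
  write_interpretation(bundle, dir)
  for (f in c("kernels.tsv", "pooled_class0.tsv", "pooled_class1.tsv",
              "weighted_pooled.tsv", "inputs_by_class.tsv",
              "interpretation.json")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  tab <- utils::read.table(file.path(dir, "kernels.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(dim(tab), c(4, 3))
})
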