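# hand-built channel_result for selection tests
fake_result <- function(channel, accuracy) {
  structure(list(channel = as.integer(channel),
                 channel_label = paste0("CH", channel),
                 fold_predictions = data.frame(), accuracy = accuracy),
            class = "channel_result")
}

test_that("LOOCV runs one fold per subject with disjoint exhaustive test sets", {
  coh <- simulate_cohort(small_sim_config(discriminative_channels = 2,
                                          effect_amplitude = 0.08,
                                          noise = noise_off(), seed = 19))
  res <- loocv_channel(coh, 2, fast_cnn_config(), base_seed = 4)
  expect_equal(nrow(res$fold_predictions), 8)
  expect_setequal(res$fold_predictions$subject,
                  vapply(coh$recordings, function(r) r$subject_id, character(1)))
  expect_equal(res$accuracy, mean(res$fold_predictions$predicted ==
                                    res$fold_predictions$true))
  expect_equal(res$accuracy, 1)

  few <- simulate_cohort(small_sim_config(n_per_group = 1, seed = 2))
  expect_error(loocv_channel(few, 1, fast_cnn_config()), "at least 2")
})

test_that("a null channel's accuracy stays inside the chance binomial band", {
  coh <- simulate_cohort(simulation_config(n_channels = 2,
                                           effect_amplitude = 0, seed = 23))
  res <- loocv_channel(coh, 1, cnn_config(epochs = 200), base_seed = 3)
  # 95% binomial interval around 0.5 for 22 folds
  band <- stats::qbinom(c(0.025, 0.975), 22, 0.5) / 22
  expect_gte(res$accuracy, band[1])
  expect_lte(res$accuracy, band[2])
})

test_that("channels rank by accuracy with index tie-breaks", {
  rep1 <- rank_channels(list(fake_result(1, 0.6), fake_result(2, 0.9),
                             fake_result(3, 0.9)))
  expect_equal(rep1$ranked$channel, c(2, 3, 1))
  rep2 <- rank_channels(list(fake_result(3, 0.7), fake_result(1, 0.7),
                             fake_result(2, 0.7)))
  expect_equal(rep2$ranked$channel, c(1, 2, 3))
  expect_error(rank_channels(list()), "non-empty")
})

test_that("ROI selection honours top-k with boundary ties and thresholds", {
  rep1 <- rank_channels(list(fake_result(1, 0.95), fake_result(2, 0.7),
                             fake_result(3, 0.5)))
  expect_equal(select_roi(rep1, "topk", 1)$selected, 1L)
  expect_equal(select_roi(rep1, "threshold", 0)$selected, c(1L, 2L, 3L))
  expect_equal(select_roi(rep1, "threshold", 0.6)$selected, c(1L, 2L))
  # three-way tie across the k = 2 boundary includes all tied channels
  rep2 <- rank_channels(list(fake_result(1, 0.8), fake_result(2, 0.8),
                             fake_result(3, 0.8), fake_result(4, 0.4)))
  expect_equal(select_roi(rep2, "topk", 2)$selected, c(1L, 2L, 3L))
  expect_error(select_roi(rep1, "topk", 0), "param")
  expect_error(select_roi(rep1, "threshold", 1.5), "threshold")
})

test_that("planted channels outrank null channels across repeated cohorts", {
  ranks_planted <- numeric(0)
  ranks_null <- numeric(0)
  for (i in 1:6) {
    coh <- simulate_cohort(small_sim_config(
      discriminative_channels = 2, effect_amplitude = 0.06, seed = 40 + i))
    res <- scan_channels(coh, config = fast_cnn_config(),
                         base_seed = mix_seed(40 + i, 1))
    ranked <- rank_channels(res)$ranked$channel
    ranks_planted <- c(ranks_planted, which(ranked == 2))
    ranks_null <- c(ranks_null, which(ranked == 1), which(ranked == 3))
  }
  expect_lt(mean(ranks_planted), mean(ranks_null))
})

test_that("ROI reports serialize with a per-channel accuracy table", {
  dir <- withr::local_tempdir()
  rep1 <- select_roi(rank_channels(list(fake_result(1, 0.9),
                                        fake_result(2, 0.4))), "topk", 1)
  write_roi_report(rep1, dir)
  tab <- utils::read.table(file.path(dir, "accuracy_by_channel.tsv"),
                           header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$channel, c(1, 2))
  obj <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(unlist(obj$selected), 1)
})
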