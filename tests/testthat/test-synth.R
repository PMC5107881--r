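test_that("task schedule durations sum to the session length", {
  sched <- task_schedule()
  expect_equal(total_duration(sched), 30 + 30 * (3 + 1 + 7) + 30)
  expect_error(task_schedule(memorize_s = 0), "memorize_s")
})

test_that("hemodynamic kernel peaks at 1 near the requested time and decays", {
  h <- hemodynamic_kernel(10, peak_s = 6, undershoot_s = 16,
                          undershoot_ratio = 1 / 6)
  expect_equal(max(h), 1)
  expect_lt(abs((which.max(h) - 1) / 10 - 6), 1)
  expect_lt(abs(h[length(h)]), 0.05)
  expect_true(all(hemodynamic_kernel(10, 6, 16, 0) >= 0))
  expect_error(hemodynamic_kernel(-1, 6, 16, 0.1), "sampling_rate_hz")
  expect_error(hemodynamic_kernel(10, 20, 16, 0.1), "peak_s")
})

test_that("kernel convolved with a boxcar matches a direct-summation oracle", {
  h <- hemodynamic_kernel(10, 6, 16, 1 / 6)
  box <- c(rep(0, 10), rep(1, 30), rep(0, 200))
  got <- nirscnn:::convolve_regressor(box, h)
  # direct double loop: out[t] = sum_a box[t - a + 1] * h[a]
  want <- numeric(length(box))
  for (t in seq_along(box)) {
    for (a in seq_along(h)) {
      if (t - a + 1 >= 1) want[t] <- want[t] + box[t - a + 1] * h[a]
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(sum(got), sum(want))
})

test_that("simulated recordings have the scheduled length and metadata", {
  cfg <- small_sim_config(seed = 3)
  rec <- simulate_subject(cfg, 1, subject_seed = 42, subject_id = "X")
  expect_s3_class(rec, "fnirs_recording")
  expect_equal(nrow(rec$data), 390 * 10)
  expect_equal(ncol(rec$data), 3)
  expect_equal(rec$task_onset_s, 30)
  expect_equal(rec$label, 1L)
  expect_error(simulate_subject(cfg, 2, 1), "group_label")
})

test_that("cohorts have the configured shape and are seed-deterministic", {
  cfg <- simulation_config(seed = 9)
  coh <- simulate_cohort(cfg)
  expect_length(coh$recordings, 22)
  expect_equal(sum(cohort_labels(coh) == 0), 11)
  expect_equal(sum(cohort_labels(coh) == 1), 11)

  tiny <- simulate_cohort(small_sim_config(n_per_group = 1, seed = 5))
  expect_length(tiny$recordings, 2)

  a <- simulate_cohort(small_sim_config(seed = 7))
  b <- simulate_cohort(small_sim_config(seed = 7))
  expect_identical(a, b)
  c2 <- simulate_cohort(small_sim_config(seed = 8))
  expect_false(identical(a$recordings[[1]]$data, c2$recordings[[1]]$data))
})

test_that("zero effect amplitude yields label-independent recordings", {
  cfg <- small_sim_config(effect_amplitude = 0,
                          discriminative_channels = c(1, 2), seed = 13)
  r0 <- simulate_subject(cfg, 0, subject_seed = 77)
  r1 <- simulate_subject(cfg, 1, subject_seed = 77)
  expect_identical(r0$data, r1$data)
})

test_that("group mean difference vanishes on null cohorts as n grows", {
  cfg <- simulation_config(n_per_group = 200, n_channels = 2,
                           effect_amplitude = 0, seed = 31)
  coh <- simulate_cohort(cfg)
  labs <- cohort_labels(coh)
  for (ch in 1:2) {
    subj_means <- vapply(coh$recordings, function(r) mean(r$data[, ch]),
                         numeric(1))
    d <- mean(subj_means[labs == 1]) - mean(subj_means[labs == 0])
    se <- sqrt(stats::var(subj_means[labs == 0]) / 200 +
                 stats::var(subj_means[labs == 1]) / 200)
    expect_lt(abs(d), 3 * se)
  }
})

test_that("noise-free group difference is exactly the designed effect template", {
  cfg <- small_sim_config(discriminative_channels = 2,
                          effect_amplitude = 0.08, noise = noise_off(),
                          seed = 17)
  r0 <- simulate_subject(cfg, 0, subject_seed = 1)
  r1 <- simulate_subject(cfg, 1, subject_seed = 1)
  template <- group_effect_template(cfg, 1)
  # planted channel differs by the template; others are identical
  expect_equal(r1$data[, 2] - r0$data[, 2], template, tolerance = 1e-12)
  expect_identical(r1$data[, 1], r0$data[, 1])
  expect_identical(r1$data[, 3], r0$data[, 3])
  # the divergence is confined to the effect window (plus response lag)
  fs <- cfg$sampling_rate_hz
  w_on <- 30 + 0.5 * 330
  expect_true(all(template[seq_len(round(w_on * fs))] == 0))
  expect_lt(min(template), 0)
})

test_that("cohort text round trip preserves data, labels and config", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(small_sim_config(n_per_group = 2, seed = 21))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_length(back$recordings, 4)
  expect_equal(cohort_labels(back), cohort_labels(coh))
  expect_equal(back$recordings[[1]]$data, coh$recordings[[1]]$data,
               tolerance = 1e-12)
  expect_equal(back$config$n_channels, coh$config$n_channels)
  expect_equal(back$config$noise$white_sd, coh$config$noise$white_sd)
})
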