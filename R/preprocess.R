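#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward ([signal::filtfilt()]),
#' so response peaks are not shifted relative to task events. The default
#' 1 Hz cutoff removes cardiac pulsation from 10 Hz oxy-Hb recordings.
#'
#' @param series numeric vector.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param cutoff_hz cutoff frequency; must lie strictly below the Nyquist
#'   frequency.
#' @param order filter order of the underlying Butterworth design.
#' @return filtered series, same length as the input.
#' @export
lowpass_filter <- function(series, sampling_rate_hz, cutoff_hz = 1.0,
                           order = 4) {
  check_that(is.numeric(series) && length(series) > 0,
             "'series' must be a non-empty numeric vector")
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_scalar(cutoff_hz, "cutoff_hz", positive = TRUE)
  check_that(cutoff_hz < sampling_rate_hz / 2,
             "'cutoff_hz' must be below the Nyquist frequency")
  # filtfilt needs some run-in; fall back to the identity for tiny inputs
  if (length(series) <= 3 * (order + 1)) return(series)
  bf <- signal::butter(order, W = cutoff_hz / (sampling_rate_hz / 2),
                       type = "low")
  # filter around the mean: filtfilt's zero initial conditions otherwise
  # produce edge transients proportional to the DC offset
  mu <- mean(series)
  signal::filtfilt(bf, series - mu) + mu
}

#' Centered moving average with shrinking edge windows
#'
#' Each output sample is the mean of the input samples inside a window of
#' `window_s` seconds centered on it; at the edges the window shrinks to the
#' available samples, so the output has the same length as the input.
#'
#' @param series numeric vector.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param window_s window length in seconds; must cover at least one sample.
#' @return smoothed series, same length as the input.
#' @export
moving_average <- function(series, sampling_rate_hz, window_s = 10) {
  check_that(is.numeric(series) && length(series) > 0,
             "'series' must be a non-empty numeric vector")
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_scalar(window_s, "window_s", positive = TRUE)
  w <- round(window_s * sampling_rate_hz)
  check_that(w >= 1, "'window_s' must cover at least one sample")
  n <- length(series)
  # even windows take the extra sample from the past, keeping the smoother
  # causal-leaning at the edges
  half_lo <- ceiling((w - 1) / 2)
  half_hi <- floor((w - 1) / 2)
  cs <- cumsum(c(0, series))
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Construct a feature series
#'
#' The 1 x N per-channel feature vector consumed by the CNN classifier.
#'
#' @param values numeric vector of N features.
#' @param channel channel identifier.
#' @param subject subject identifier.
#' @param label group label 0/1 or `NA`.
#' @return an object of class `feature_series`.
#' @export
feature_series <- function(values, channel = NA, subject = NA, label = NA) {
  check_that(is.numeric(values) && length(values) >= 1,
             "'values' must be a non-empty numeric vector")
  structure(list(values = as.numeric(values), channel = channel,
                 subject = subject,
                 label = if (is.na(label)) NA_integer_ else as.integer(label)),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("feature_series: N = %d, channel %s, subject %s, label %s\n",
              length(x$values), x$channel, x$subject,
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' Windowed feature extraction
#'
#' Collapses a sampled series into N window means: starting at `start_s`,
#' consecutive non-overlapping windows of `window_s` seconds are averaged,
#' yielding one feature per window (1 s windows at 10 Hz downsample to 1 Hz).
#'
#' @param series numeric vector (one channel's samples).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param window_s feature window length in seconds.
#' @param start_s offset of the first window from the start of the series,
#'   in seconds (typically the task onset).
#' @param duration_s total extracted duration; must be a multiple of
#'   `window_s` and fit inside the recording.
#' @return numeric vector of `duration_s / window_s` features.
#' @export
extract_features <- function(series, sampling_rate_hz, window_s = 1,
                             start_s = 0, duration_s) {
  check_that(is.numeric(series) && length(series) > 0,
             "'series' must be a non-empty numeric vector")
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_scalar(window_s, "window_s", positive = TRUE)
  check_scalar(start_s, "start_s", nonneg = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  n_feat <- duration_s / window_s
  check_that(abs(n_feat - round(n_feat)) < 1e-8,
             "'duration_s' must be a whole multiple of 'window_s'")
  n_feat <- round(n_feat)
  w <- round(window_s * sampling_rate_hz)
  first <- round(start_s * sampling_rate_hz) + 1
  last <- first + n_feat * w - 1
  check_that(last <= length(series),
             "feature window extends past the end of the recording")
  colMeans(matrix(series[first:last], nrow = w))
}

#' Min-max normalization to [0, 1]
#'
#' Rescales a feature series so its minimum is 0 and maximum is 1. A
#' constant (degenerate) series is mapped to 0.5 everywhere with a warning
#' rather than an error, so noise-free null simulations pass through.
#'
#' @param x a [feature_series()] or numeric vector.
#' @return same type as the input, normalized.
#' @export
minmax_normalize <- function(x) {
  if (inherits(x, "feature_series")) {
    x$values <- minmax_normalize(x$values)
    return(x)
  }
  check_that(is.numeric(x) && length(x) >= 1, "input must be numeric")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant series: min-max normalization degenerate, returning 0.5")
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Full preprocessing chain for one channel of a recording
#'
#' Applies, in order: zero-phase low-pass filtering, centered moving
#' average, windowed feature extraction from `start_s`, and min-max
#' normalization. This is the fixed pipeline that turns a raw oxy-Hb trace
#' into the CNN's 1 x N input.
#'
#' @param recording an [fnirs_recording()].
#' @param channel channel index.
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param mov_avg_s moving-average window (seconds).
#' @param feature_window_s feature window (seconds).
#' @param start_s start of the feature window; defaults to the recording's
#'   task onset.
#' @param duration_s extracted duration (seconds).
#' @return a [feature_series()] of N = `duration_s / feature_window_s`
#'   normalized values.
#' @export
preprocess_channel <- function(recording, channel, cutoff_hz = 1.0,
                               mov_avg_s = 10, feature_window_s = 1,
                               start_s = recording$task_onset_s,
                               duration_s = 200) {
  stopifnot(inherits(recording, "fnirs_recording"))
  check_scalar(channel, "channel", positive = TRUE, integerish = TRUE)
  check_that(channel <= ncol(recording$data), "channel index out of range")
  fs <- recording$sampling_rate_hz
  x <- recording$data[, channel]
  x <- lowpass_filter(x, fs, cutoff_hz)
  x <- moving_average(x, fs, mov_avg_s)
  vals <- extract_features(x, fs, window_s = feature_window_s,
                           start_s = start_s, duration_s = duration_s)
  feature_series(minmax_normalize(vals),
                 channel = recording$channel_labels[channel],
                 subject = recording$subject_id, label = recording$label)
}

#' Per-channel feature matrix for a whole cohort
#'
#' Runs [preprocess_channel()] on one channel of every subject and stacks
#' the results into a subjects x N matrix. Normalization is per subject, so
#' no statistic crosses subjects and cross-validation cannot leak.
#'
#' @param cohort an `fnirs_cohort`.
#' @param channel channel index.
#' @param ... preprocessing parameters passed to [preprocess_channel()].
#' @return a list with `x` (subjects x N matrix), `labels` (integer vector)
#'   and `subjects` (ids).
#' @export
cohort_features <- function(cohort, channel, ...) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  fs_list <- lapply(cohort$recordings, preprocess_channel, channel = channel, ...)
  x <- do.call(rbind, lapply(fs_list, function(f) f$values))
  rownames(x) <- vapply(cohort$recordings, function(r) as.character(r$subject_id),
                        character(1))
  list(x = x, labels = cohort_labels(cohort), subjects = rownames(x))
}

#' Write per-channel feature tables for a cohort
#'
#' One tab-separated table per channel (subjects x N features, subject ids in
#' the first column) plus a JSON sidecar with the parameters and label map.
#'
#' @param cohort an `fnirs_cohort`.
#' @param dir output directory.
#' @param channels channel indices to export; default all.
#' @param ... preprocessing parameters passed to [preprocess_channel()].
#' @return invisibly, the sidecar path.
#' @export
write_features <- function(cohort, dir, channels = NULL, ...) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  if (is.null(channels)) channels <- seq_len(cohort$config$n_channels)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(...)
  files <- character(0)
  for (ch in channels) {
    feats <- cohort_features(cohort, ch, ...)
    file <- sprintf("features_CH%02d.tsv", ch)
    tab <- data.frame(subject = feats$subjects, feats$x, check.names = FALSE)
    colnames(tab)[-1] <- paste0("f", seq_len(ncol(feats$x)))
    utils::write.table(tab, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, file)
  }
  labels_tab <- data.frame(
    subject = vapply(cohort$recordings, function(r) as.character(r$subject_id),
                     character(1)),
    label = cohort_labels(cohort))
  utils::write.table(labels_tab, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sidecar <- list(channels = channels, files = files, parameters = params,
                  labels = as.list(stats::setNames(
                    cohort_labels(cohort),
                    vapply(cohort$recordings,
                           function(r) as.character(r$subject_id), character(1)))))
  path <- file.path(dir, "features.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
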