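#' Construct an fNIRS recording object
#'
#' Container for one subject's multi-channel oxy-Hb concentration-change
#' recording. The data matrix holds time in rows and channels in columns.
#'
#' @param data numeric matrix, samples x channels.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param channel_labels character vector of channel names; default
#'   `"CH1".."CHn"`.
#' @param task_onset_s time of task onset (end of the initial rest), seconds.
#' @param label group label 0 or 1, or `NA` for unlabeled data.
#' @param subject_id subject identifier.
#' @param seed the RNG seed the recording was generated with, if any.
#' @return an object of class `fnirs_recording`.
#' @export
fnirs_recording <- function(data, sampling_rate_hz, channel_labels = NULL,
                            task_onset_s = 0, label = NA, subject_id = NA,
                            seed = NA) {
  data <- as.matrix(data)
  check_that(is.numeric(data) && nrow(data) >= 1, "'data' must be a numeric matrix")
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_that(task_onset_s >= 0 &&
               task_onset_s <= nrow(data) / sampling_rate_hz,
             "'task_onset_s' must fall within the recording")
  if (is.null(channel_labels)) channel_labels <- paste0("CH", seq_len(ncol(data)))
  check_that(length(channel_labels) == ncol(data),
             "'channel_labels' must name every column of 'data'")
  check_that(is.na(label) || label %in% c(0, 1), "'label' must be 0, 1 or NA")
  colnames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate_hz = sampling_rate_hz,
         channel_labels = channel_labels, task_onset_s = task_onset_s,
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         subject_id = subject_id, seed = seed),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf(
    "fnirs_recording '%s': %d channels x %d samples @ %g Hz, label %s\n",
    x$subject_id, ncol(x$data), nrow(x$data), x$sampling_rate_hz,
    ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' Deterministic group-effect template of a simulated recording
#'
#' The noise-free signal a discriminative channel adds on top of the common
#' task response, as a function of group. Group 0 carries no extra signal;
#' group 1 carries a negative-going hemodynamic deflection of amplitude
#' `effect_amplitude` restricted to `effect_window` within the task period,
#' so the groups diverge only in that window (by default the latter half of
#' the task, where one group's response falls away while the other's stays
#' near baseline).
#'
#' @param config a [simulation_config()].
#' @param group group label, 0 or 1.
#' @return numeric vector over the full session (length = duration x rate).
#' @export
group_effect_template <- function(config, group) {
  stopifnot(inherits(config, "simulation_config"))
  check_that(group %in% c(0, 1), "'group' must be 0 or 1")
  fs <- config$sampling_rate_hz
  n <- round(total_duration(config$schedule) * fs)
  if (group == 0 || config$effect_amplitude == 0) return(numeric(n))
  sched <- config$schedule
  box <- task_boxcar(sched, fs)
  t <- (seq_len(n) - 1) / fs
  task_len <- sched$n_trials * (sched$memorize_s + sched$retain_s + sched$respond_s)
  w_on <- sched$pre_rest_s + config$effect_window[1] * task_len
  w_off <- sched$pre_rest_s + config$effect_window[2] * task_len
  box[t < w_on | t >= w_off] <- 0
  h <- hemodynamic_kernel(fs)
  -config$effect_amplitude * convolve_regressor(box, h)
}

#' Simulate one subject's fNIRS recording
#'
#' Builds the task-evoked oxy-Hb response (boxcar task regressor convolved
#' with a hemodynamic kernel, amplitude `base_amplitude`, identical on every
#' channel), adds the group-effect template on the discriminative channels,
#' and layers on drift, sinusoidal physiological oscillations with random
#' phases, and white noise per channel.
#'
#' @param config a [simulation_config()].
#' @param group_label group membership, 0 or 1.
#' @param subject_seed integer seed for this subject's noise draws.
#' @param subject_id identifier stored in the recording.
#' @return an [fnirs_recording()].
#' @export
simulate_subject <- function(config, group_label, subject_seed,
                             subject_id = NA) {
  stopifnot(inherits(config, "simulation_config"))
  check_that(group_label %in% c(0, 1), "'group_label' must be 0 or 1")
  check_scalar(subject_seed, "subject_seed", integerish = TRUE)
  fs <- config$sampling_rate_hz
  n <- round(total_duration(config$schedule) * fs)
  t <- (seq_len(n) - 1) / fs

  h <- hemodynamic_kernel(fs)
  common <- config$base_amplitude *
    convolve_regressor(task_boxcar(config$schedule, fs), h)
  effect <- group_effect_template(config, group_label)

  ns <- config$noise
  set.seed(as.integer(subject_seed))
  data <- matrix(0, n, config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    sig <- common
    if (ch %in% config$discriminative_channels) sig <- sig + effect
    # phases drawn even when amplitudes are 0, so the RNG stream (and hence
    # the white noise) is identical between noisy and partially-noisy setups
    phases <- stats::runif(4, 0, 2 * pi)
    drift <- ns$drift_amplitude * sin(2 * pi * t / ns$drift_period_s + phases[1])
    physio <- ns$physio_amplitudes[1] * sin(2 * pi * ns$cardiac_hz * t + phases[2]) +
      ns$physio_amplitudes[2] * sin(2 * pi * ns$respiratory_hz * t + phases[3]) +
      ns$physio_amplitudes[3] * sin(2 * pi * ns$mayer_hz * t + phases[4])
    white <- if (ns$white_sd > 0) stats::rnorm(n, 0, ns$white_sd) else numeric(n)
    data[, ch] <- sig + drift + physio + white
  }
  fnirs_recording(data, fs, task_onset_s = config$schedule$pre_rest_s,
                  label = group_label, subject_id = subject_id,
                  seed = as.integer(subject_seed))
}

#' Simulate a labeled two-group cohort
#'
#' Generates `n_per_group` subjects with label 0 followed by `n_per_group`
#' with label 1. Each subject's seed is derived deterministically from the
#' cohort seed and the subject index, so individual subjects can be
#' regenerated in isolation and the whole cohort is reproducible.
#'
#' @param config a [simulation_config()].
#' @return an object of class `fnirs_cohort`: a list with elements
#'   `recordings` (list of [fnirs_recording()]) and `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_per_group = 2, n_channels = 3))
#' length(cohort$recordings) # 4
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- rep(c(0L, 1L), each = config$n_per_group)
  recs <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    recs[[i]] <- simulate_subject(
      config, labels[i], subject_seed = mix_seed(config$seed, i),
      subject_id = sprintf("S%02d", i))
  }
  structure(list(recordings = recs, config = config), class = "fnirs_cohort")
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  labs <- vapply(x$recordings, function(r) r$label, integer(1))
  cat(sprintf("fnirs_cohort: %d subjects (%d / %d per group), %d channels\n",
              length(labs), sum(labs == 0), sum(labs == 1),
              x$config$n_channels))
  invisible(x)
}

#' Cohort group labels
#' @param cohort an `fnirs_cohort`.
#' @return integer vector of per-subject labels.
#' @export
cohort_labels <- function(cohort) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  vapply(cohort$recordings, function(r) r$label, integer(1))
}

#' Write a cohort to disk as delimited text plus a JSON manifest
#'
#' Each subject becomes one tab-separated file with a `time_s` column and one
#' column per channel; `manifest.json` records subject ids, files, labels,
#' seeds and an echo of the simulation configuration.
#'
#' @param cohort an `fnirs_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (rec in cohort$recordings) {
    file <- paste0(rec$subject_id, ".tsv")
    tab <- data.frame(
      time_s = (seq_len(nrow(rec$data)) - 1) / rec$sampling_rate_hz,
      rec$data, check.names = FALSE)
    utils::write.table(tab, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    entries[[length(entries) + 1]] <- list(
      subject = rec$subject_id, file = file, label = rec$label,
      seed = rec$seed)
  }
  manifest <- list(
    subjects = entries,
    sampling_rate_hz = cohort$config$sampling_rate_hz,
    task_onset_s = cohort$config$schedule$pre_rest_s,
    config = config_to_list(cohort$config))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort previously written by [write_cohort()]
#' @param dir directory containing subject files and `manifest.json`.
#' @return an `fnirs_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  fs <- manifest$sampling_rate_hz
  onset <- manifest$task_onset_s
  recs <- lapply(manifest$subjects, function(e) {
    tab <- utils::read.table(file.path(dir, e$file), header = TRUE, sep = "\t",
                             check.names = FALSE)
    fnirs_recording(as.matrix(tab[, -1, drop = FALSE]), fs,
                    channel_labels = colnames(tab)[-1], task_onset_s = onset,
                    label = e$label, subject_id = e$subject,
                    seed = if (is.null(e$seed)) NA else e$seed)
  })
  config <- config_from_list(manifest$config)
  structure(list(recordings = recs, config = config), class = "fnirs_cohort")
}

# internal: (de)serialize a simulation_config through plain lists for JSON/YAML
config_to_list <- function(config) {
  list(
    n_per_group = config$n_per_group, n_channels = config$n_channels,
    sampling_rate_hz = config$sampling_rate_hz,
    schedule = unclass(config$schedule),
    discriminative_channels = config$discriminative_channels,
    effect_amplitude = config$effect_amplitude,
    effect_window = config$effect_window,
    base_amplitude = config$base_amplitude,
    noise = unclass(config$noise), seed = config$seed)
}

config_from_list <- function(x) {
  simulation_config(
    n_per_group = x$n_per_group, n_channels = x$n_channels,
    sampling_rate_hz = x$sampling_rate_hz,
    schedule = do.call(task_schedule, as_plain_list(x$schedule)),
    discriminative_channels = unlist(x$discriminative_channels),
    effect_amplitude = x$effect_amplitude,
    effect_window = unlist(x$effect_window),
    base_amplitude = x$base_amplitude,
    noise = do.call(noise_spec, as_plain_list(x$noise)), seed = x$seed)
}

as_plain_list <- function(x) {
  lapply(x, function(v) if (is.list(v)) unlist(v) else v)
}
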