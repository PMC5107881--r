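#' Block-design task schedule
#'
#' Describes the timing of a block-design cognitive task: an initial rest
#' phase, `n_trials` repetitions of a memorize/retain/respond trial, and a
#' final rest phase. The defaults encode a number-memory task: 30 s rest,
#' 30 trials of 3 s memorize + 1 s retain + 7 s respond, then 30 s rest,
#' for a 390 s session.
#'
#' @param pre_rest_s initial rest duration in seconds.
#' @param n_trials number of task trials.
#' @param memorize_s,retain_s,respond_s per-trial phase durations in seconds.
#' @param post_rest_s final rest duration in seconds.
#' @return an object of class `task_schedule`.
#' @examples
#' sched <- task_schedule()
#' total_duration(sched) # 390 s
#' @export
task_schedule <- function(pre_rest_s = 30, n_trials = 30, memorize_s = 3,
                          retain_s = 1, respond_s = 7, post_rest_s = 30) {
  check_scalar(pre_rest_s, "pre_rest_s", positive = TRUE)
  check_scalar(n_trials, "n_trials", positive = TRUE, integerish = TRUE)
  check_scalar(memorize_s, "memorize_s", positive = TRUE)
  check_scalar(retain_s, "retain_s", positive = TRUE)
  check_scalar(respond_s, "respond_s", positive = TRUE)
  check_scalar(post_rest_s, "post_rest_s", positive = TRUE)
  structure(
    list(pre_rest_s = pre_rest_s, n_trials = as.integer(n_trials),
         memorize_s = memorize_s, retain_s = retain_s, respond_s = respond_s,
         post_rest_s = post_rest_s),
    class = "task_schedule"
  )
}

#' Total session duration of a task schedule, in seconds
#' @param schedule a [task_schedule()].
#' @return duration in seconds.
#' @export
total_duration <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  trial_s <- schedule$memorize_s + schedule$retain_s + schedule$respond_s
  schedule$pre_rest_s + schedule$n_trials * trial_s + schedule$post_rest_s
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf(
    "task_schedule: %gs rest + %d x (%g+%g+%g)s trials + %gs rest = %gs\n",
    x$pre_rest_s, x$n_trials, x$memorize_s, x$retain_s, x$respond_s,
    x$post_rest_s, total_duration(x)))
  invisible(x)
}

#' Physiological and instrumental noise specification for the simulator
#'
#' Additive confounds layered on top of the task-evoked response: white
#' measurement noise, a slow sinusoidal baseline drift, and sinusoidal
#' cardiac (~1 Hz), respiratory (~0.3 Hz) and Mayer-wave (~0.1 Hz)
#' components with subject- and channel-specific random phases. Amplitudes
#' are in the same relative oxy-Hb concentration units as the signal.
#'
#' @param white_sd standard deviation of white noise.
#' @param drift_amplitude,drift_period_s amplitude and period of the slow
#'   baseline drift.
#' @param cardiac_hz,respiratory_hz,mayer_hz centre frequencies of the three
#'   physiological oscillations.
#' @param physio_amplitudes length-3 numeric: amplitudes of the cardiac,
#'   respiratory and Mayer components, in that order.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 0.05, drift_amplitude = 0.03,
                       drift_period_s = 120, cardiac_hz = 1.0,
                       respiratory_hz = 0.3, mayer_hz = 0.1,
                       physio_amplitudes = c(0.02, 0.02, 0.03)) {
  check_scalar(white_sd, "white_sd", nonneg = TRUE)
  check_scalar(drift_amplitude, "drift_amplitude", nonneg = TRUE)
  check_scalar(drift_period_s, "drift_period_s", positive = TRUE)
  check_scalar(cardiac_hz, "cardiac_hz", positive = TRUE)
  check_scalar(respiratory_hz, "respiratory_hz", positive = TRUE)
  check_scalar(mayer_hz, "mayer_hz", positive = TRUE)
  check_that(is.numeric(physio_amplitudes) && length(physio_amplitudes) == 3 &&
               all(physio_amplitudes >= 0),
             "'physio_amplitudes' must be 3 non-negative amplitudes")
  structure(
    list(white_sd = white_sd, drift_amplitude = drift_amplitude,
         drift_period_s = drift_period_s, cardiac_hz = cardiac_hz,
         respiratory_hz = respiratory_hz, mayer_hz = mayer_hz,
         physio_amplitudes = as.numeric(physio_amplitudes)),
    class = "noise_spec"
  )
}

#' Noise specification with every amplitude set to zero
#'
#' Convenience constructor for noiseless simulations, where recordings are
#' fully determined by the task design and group effect.
#' @return a [noise_spec()] with all amplitudes 0.
#' @export
noise_off <- function() {
  noise_spec(white_sd = 0, drift_amplitude = 0, physio_amplitudes = c(0, 0, 0))
}

#' Simulation configuration for a two-group fNIRS cohort
#'
#' Defines the cohort shape, acquisition parameters, which channels carry a
#' group-dependent response, and how strong that effect is. Defaults encode
#' a 2 x 11 subject cohort measured on 24 channels at 10 Hz, with the group
#' effect confined to the latter half of the task period.
#'
#' @param n_per_group subjects per group (two groups, labels 0 and 1).
#' @param n_channels number of measurement channels.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param schedule a [task_schedule()].
#' @param discriminative_channels integer vector of channel indices that carry
#'   the group effect.
#' @param effect_amplitude size of the group effect in oxy-Hb units; 0 yields
#'   a null cohort where both groups are drawn from the same distribution.
#' @param effect_window length-2 numeric in [0, 1]: the fraction of the task
#'   period (rest excluded) over which the groups diverge. Default latter half.
#' @param base_amplitude amplitude of the task-evoked response common to all
#'   channels and both groups.
#' @param noise a [noise_spec()].
#' @param seed integer cohort seed; subject seeds are derived from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 11, n_channels = 24,
                              sampling_rate_hz = 10,
                              schedule = task_schedule(),
                              discriminative_channels = integer(0),
                              effect_amplitude = 0.05,
                              effect_window = c(0.5, 1),
                              base_amplitude = 0.1,
                              noise = noise_spec(), seed = 1L) {
  check_scalar(n_per_group, "n_per_group", positive = TRUE, integerish = TRUE)
  check_scalar(n_channels, "n_channels", positive = TRUE, integerish = TRUE)
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  stopifnot(inherits(schedule, "task_schedule"), inherits(noise, "noise_spec"))
  check_scalar(effect_amplitude, "effect_amplitude", nonneg = TRUE)
  check_scalar(base_amplitude, "base_amplitude", nonneg = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  dc <- as.integer(discriminative_channels)
  check_that(all(dc >= 1 & dc <= n_channels) && !anyDuplicated(dc),
             "'discriminative_channels' must be distinct indices in 1..n_channels")
  check_that(is.numeric(effect_window) && length(effect_window) == 2 &&
               effect_window[1] >= 0 && effect_window[2] <= 1 &&
               effect_window[1] < effect_window[2],
             "'effect_window' must be an increasing pair within [0, 1]")
  nyq <- sampling_rate_hz / 2
  check_that(noise$cardiac_hz < nyq && noise$respiratory_hz < nyq &&
               noise$mayer_hz < nyq,
             "noise frequencies must lie below the Nyquist frequency")
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_channels = as.integer(n_channels),
         sampling_rate_hz = sampling_rate_hz, schedule = schedule,
         discriminative_channels = dc,
         effect_amplitude = effect_amplitude,
         effect_window = as.numeric(effect_window),
         base_amplitude = base_amplitude,
         noise = noise, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: 2 x %d subjects, %d channels @ %g Hz\n",
              x$n_per_group, x$n_channels, x$sampling_rate_hz))
  cat(sprintf("  effect %.3g on channels {%s}, window [%.2f, %.2f] of task\n",
              x$effect_amplitude,
              paste(x$discriminative_channels, collapse = ", "),
              x$effect_window[1], x$effect_window[2]))
  print(x$schedule)
  invisible(x)
}
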