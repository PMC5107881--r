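#' Canonical hemodynamic impulse response
#'
#' Difference-of-gammas hemodynamic response function: a gamma-shaped rise
#' peaking at `peak_s` minus a later, smaller gamma-shaped undershoot
#' peaking at `undershoot_s`. The kernel is normalized so its maximum is 1
#' and truncated where the response has decayed to a negligible level.
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @param peak_s time-to-peak of the positive lobe, seconds.
#' @param undershoot_s time-to-peak of the undershoot lobe, seconds; must
#'   exceed `peak_s`.
#' @param undershoot_ratio amplitude of the undershoot relative to the peak
#'   (0 disables the undershoot and the kernel is non-negative).
#' @param duration_s kernel length in seconds (default twice `undershoot_s`,
#'   long enough for the undershoot to recover toward 0).
#' @return numeric vector: the impulse response sampled at `sampling_rate_hz`,
#'   starting at lag 0, with `max(kernel) == 1`.
#' @examples
#' h <- hemodynamic_kernel(10, 6, 16, 1 / 6)
#' which.max(h) # close to 6 s * 10 Hz
#' @export
hemodynamic_kernel <- function(sampling_rate_hz, peak_s = 6, undershoot_s = 16,
                               undershoot_ratio = 1 / 6,
                               duration_s = 2 * undershoot_s) {
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_scalar(peak_s, "peak_s", positive = TRUE)
  check_scalar(undershoot_s, "undershoot_s", positive = TRUE)
  check_scalar(undershoot_ratio, "undershoot_ratio", nonneg = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_that(peak_s < undershoot_s, "'peak_s' must be < 'undershoot_s'")

  t <- seq(0, duration_s, by = 1 / sampling_rate_hz)
  # gamma lobes parameterized by their mode: mode = (shape - 1) / rate
  shape1 <- 6; shape2 <- 16
  g1 <- stats::dgamma(t, shape = shape1, rate = (shape1 - 1) / peak_s)
  g2 <- stats::dgamma(t, shape = shape2, rate = (shape2 - 1) / undershoot_s)
  h <- g1 / max(g1) - undershoot_ratio * g2 / max(g2)
  h / max(h)
}

# internal: 0/1 task regressor over the session, active during each trial's
# memorize + retain phases (the encoding load the hemodynamic response follows)
task_boxcar <- function(schedule, sampling_rate_hz) {
  n <- round(total_duration(schedule) * sampling_rate_hz)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  trial_s <- schedule$memorize_s + schedule$retain_s + schedule$respond_s
  active_s <- schedule$memorize_s + schedule$retain_s
  box <- numeric(n)
  for (k in seq_len(schedule$n_trials)) {
    on <- schedule$pre_rest_s + (k - 1) * trial_s
    box[t >= on & t < on + active_s] <- 1
  }
  box
}

# internal: causal convolution of a regressor with a kernel, truncated to the
# regressor's length (lag-0 aligned). Time-domain (not FFT) so zero inputs
# convolve to exact zeros.
convolve_regressor <- function(regressor, kernel) {
  n <- length(regressor)
  m <- length(kernel)
  padded <- c(rep(0, m - 1), regressor)
  out <- stats::filter(padded, kernel, method = "convolution", sides = 1)
  as.numeric(out[m:(n + m - 1)])
}
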