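#' Build a motor-unit pool for one muscle
#'
#' Draws a pool of motor units whose properties encode the group contrast:
#' sarcopenic pools contain fewer units (denervation), each with larger
#' MUAP amplitude (reinnervation enlarges surviving units), longer MUAP
#' duration (fibre-type shift toward slow fibres lowers spectral content)
#' and slightly lower firing rates. Recruitment follows the size principle:
#' thresholds are sorted ascending and MUAP amplitude increases
#' monotonically with threshold, so low-threshold units are small.
#'
#' Given the same `seed` and equal pool sizes, the sarcopenic pool is the
#' healthy pool with durations multiplied by `duration_scale_sarcopenic`,
#' amplitudes by `amplitude_scale_sarcopenic` and rates by 0.85, making the
#' group effect a pure, testable rescaling.
#'
#' @param group_label `"healthy"` or `"sarcopenia"`.
#' @param config A [sim_config()].
#' @param seed Integer seed for the pool draw.
#' @return Tibble with one row per motor unit: `unit`, `muap_amplitude`
#'   (mV), `muap_duration` (ms), `recruitment_threshold` (fraction of MVC
#'   in \[0, 1)), `mean_firing_rate` (Hz).
#' @export
build_motor_unit_pool <- function(group_label = c("healthy", "sarcopenia"),
                                  config = sim_config(), seed = 1L) {
  group_label <- match.arg(group_label)
  n <- if (group_label == "healthy") {
    config$n_motor_units_healthy
  } else {
    config$n_motor_units_sarcopenic
  }
  if (!is.finite(n) || n < 1L) abort("motor-unit count must be a positive integer")

  set.seed(seed)
  thresholds <- sort(runif(n, 0, 0.75))
  # size principle: amplitude grows monotonically with recruitment threshold
  amplitude <- config$muap_amplitude_mv * exp(1.5 * thresholds)
  duration <- config$muap_duration_ms * runif(n, 0.9, 1.1)
  rate <- runif(n, config$mean_firing_rate_hz[1], config$mean_firing_rate_hz[2])

  if (group_label == "sarcopenia") {
    duration <- duration * config$duration_scale_sarcopenic
    amplitude <- amplitude * config$amplitude_scale_sarcopenic
    rate <- rate * 0.85
  }

  tibble(
    unit = seq_len(n),
    muap_amplitude = amplitude,
    muap_duration = duration,
    recruitment_threshold = thresholds,
    mean_firing_rate = rate
  )
}

# biphasic MUAP kernel: first derivative of a Gaussian, peak-normalized.
# sigma (s) = duration_ms / 6 / 1000; support truncated at +/- 3 sigma.
# The power spectrum of this kernel is f^2 exp(-4 pi^2 sigma^2 f^2), whose
# median frequency is ~0.1731 / sigma, which is what makes median-frequency
# calibration analytic.
muap_kernel <- function(duration_ms, amplitude, sampling_rate) {
  sigma <- duration_ms / 6 / 1000
  half <- max(1L, ceiling(3 * sigma * sampling_rate))
  u <- (-half:half) / sampling_rate
  k <- -(u / sigma) * exp(-u^2 / (2 * sigma^2)) * exp(0.5)
  amplitude * k
}
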