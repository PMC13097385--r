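#' Simulation configuration for synthetic grip-test cohorts
#'
#' Bundles every tunable parameter of the synthetic-cohort generator. The
#' defaults are frozen calibration values chosen so that the simulated
#' cohort reproduces the statistical structure the downstream analysis
#' assumes: healthy-group sEMG median frequency near 90-120 Hz and
#' sarcopenic-group median frequency near 65-75 Hz, reduced raw signal
#' amplitude in the sarcopenia group, a stronger within-trial fatigue ramp
#' in the sarcopenia group (which elevates MVC-normalized amplitude
#' features), and an sEMG signal-to-noise ratio in the mid-30 dB range.
#'
#' The sarcopenia "knobs" follow motor-unit physiology: the sarcopenic pool
#' has fewer motor units, each enlarged (higher MUAP amplitude) and slower
#' (longer MUAP duration, which shifts spectral content downward), while
#' the composite signal is attenuated overall.
#'
#' @param sampling_rate Sampling rate in Hz for all four channels.
#' @param n_motor_units_healthy,n_motor_units_sarcopenic Motor-unit pool
#'   sizes per muscle.
#' @param muap_duration_ms Baseline MUAP kernel time-support (ms) for a
#'   healthy motor unit; the biphasic kernel's Gaussian scale is
#'   `muap_duration_ms / 6`.
#' @param duration_scale_sarcopenic Multiplier (> 1) on MUAP duration in the
#'   sarcopenic group; drives the median-frequency decline.
#' @param amplitude_scale_sarcopenic Per-unit MUAP amplitude multiplier in
#'   the sarcopenic group (surviving units enlarge).
#' @param amplitude_attenuation_sarcopenic Multiplier (< 1) on the
#'   sarcopenic composite signal; drives the raw-amplitude decline.
#' @param mechanical_semg_attenuation Milder composite attenuation used for
#'   the mechanical-dominant phenotype, whose electrical signature is
#'   close to normal.
#' @param phenotype_mix Named probabilities (`neural`, `mechanical`,
#'   `mixed`) of the sarcopenic presentation drawn per subject:
#'   neural-dominant cases show the full sEMG signature (amplitude loss,
#'   strong fatigue ramp) with preserved mechanical output,
#'   mechanical-dominant cases show near-normal sEMG amplitude dynamics
#'   but reduced deformation per unit force, and mixed cases show both.
#'   All sarcopenic phenotypes share the prolonged MUAP duration (the
#'   fibre-type shift), so the group's median-frequency decline is
#'   phenotype-independent.
#' @param muap_amplitude_mv Baseline MUAP peak amplitude (mV) of the
#'   lowest-threshold unit.
#' @param mean_firing_rate_hz Two-element range; each unit's mean firing
#'   rate at full recruitment is drawn uniformly from it.
#' @param firing_cv Coefficient of variation of Gamma-distributed
#'   inter-pulse intervals.
#' @param fatigue_ramp Named vector (`healthy`, `sarcopenia`): fractional
#'   amplitude rise across one contraction (0.2 = +20% by the end of the
#'   hold).
#' @param fatigue_mf_drift Named vector: fractional MUAP-duration widening
#'   across one contraction (lowers median frequency late in the hold).
#' @param noise_sd Additive Gaussian noise SD on the sEMG channels (mV).
#' @param strain_gain Piezoelectric channel gain, V per (kg/s) of grip-force
#'   rate.
#' @param strain_attenuation_sarcopenic Multiplier (< 1) on the sarcopenic
#'   strain channels: mechanical deformation per unit grip force is reduced
#'   by the loss of contractile tissue, independently of the lower absolute
#'   grip strength.
#' @param strain_tau_s Time constant (s) of the first-order rate-sensitive
#'   piezoelectric response.
#' @param strain_noise_sd Additive Gaussian noise SD on the strain
#'   channels (V).
#' @param trial_s MVC trial duration (s).
#' @param n_trials MVC trials per session.
#' @param ramp_s Effort ramp-up/down duration (s) of the trapezoidal effort
#'   profile within each trial.
#' @param rest_range_s Two-element range (s); inter-trial rests are drawn
#'   uniformly from it.
#' @param lead_in_s Quiet baseline recorded before the first trial (s).
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(sampling_rate = 1000,
                       n_motor_units_healthy = 120,
                       n_motor_units_sarcopenic = 60,
                       muap_duration_ms = 10,
                       duration_scale_sarcopenic = 1.5,
                       amplitude_scale_sarcopenic = 1.3,
                       amplitude_attenuation_sarcopenic = 0.55,
                       mechanical_semg_attenuation = 0.9,
                       phenotype_mix = c(neural = 0.3, mechanical = 0.3, mixed = 0.4),
                       muap_amplitude_mv = 0.03,
                       mean_firing_rate_hz = c(20, 30),
                       firing_cv = 0.15,
                       fatigue_ramp = c(healthy = 0.05, sarcopenia = 0.35),
                       fatigue_mf_drift = c(healthy = 0.02, sarcopenia = 0.08),
                       noise_sd = 0.004,
                       strain_gain = 0.1,
                       strain_attenuation_sarcopenic = 0.55,
                       strain_tau_s = 0.1,
                       strain_noise_sd = 0.005,
                       trial_s = 5,
                       n_trials = 3,
                       ramp_s = 0.5,
                       rest_range_s = c(4, 6),
                       lead_in_s = 2,
                       seed = 1L) {
  check_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  check_number(n_motor_units_healthy, "n_motor_units_healthy", 1)
  check_number(n_motor_units_sarcopenic, "n_motor_units_sarcopenic", 1)
  check_number(muap_duration_ms, "muap_duration_ms", 0, strict = TRUE)
  check_number(duration_scale_sarcopenic, "duration_scale_sarcopenic", 0, strict = TRUE)
  check_number(amplitude_attenuation_sarcopenic, "amplitude_attenuation_sarcopenic",
    0,
    strict = TRUE
  )
  check_number(noise_sd, "noise_sd", 0)
  if (length(rest_range_s) != 2L || diff(rest_range_s) < 0) {
    abort("`rest_range_s` must be an increasing length-2 range.")
  }
  # biphasic kernel content lives well below ~3 / (pi * sigma); at the
  # default duration that is < 500 Hz, satisfying the Nyquist constraint
  structure(
    list(
      sampling_rate = sampling_rate,
      n_motor_units_healthy = as.integer(n_motor_units_healthy),
      n_motor_units_sarcopenic = as.integer(n_motor_units_sarcopenic),
      muap_duration_ms = muap_duration_ms,
      duration_scale_sarcopenic = duration_scale_sarcopenic,
      amplitude_scale_sarcopenic = amplitude_scale_sarcopenic,
      amplitude_attenuation_sarcopenic = amplitude_attenuation_sarcopenic,
      mechanical_semg_attenuation = mechanical_semg_attenuation,
      phenotype_mix = phenotype_mix,
      muap_amplitude_mv = muap_amplitude_mv,
      mean_firing_rate_hz = mean_firing_rate_hz,
      firing_cv = firing_cv,
      fatigue_ramp = fatigue_ramp,
      fatigue_mf_drift = fatigue_mf_drift,
      noise_sd = noise_sd,
      strain_gain = strain_gain,
      strain_attenuation_sarcopenic = strain_attenuation_sarcopenic,
      strain_tau_s = strain_tau_s,
      strain_noise_sd = strain_noise_sd,
      trial_s = trial_s,
      n_trials = as.integer(n_trials),
      ramp_s = ramp_s,
      rest_range_s = rest_range_s,
      lead_in_s = lead_in_s,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d Hz, %d/%d motor units (healthy/sarcopenic), MUAP %g ms (x%g sarcopenic)\n",
    x$sampling_rate, x$n_motor_units_healthy, x$n_motor_units_sarcopenic,
    x$muap_duration_ms, x$duration_scale_sarcopenic
  ))
  cat(sprintf(
    "  %d trials x %g s, ramps %g s, rests %g-%g s\n",
    x$n_trials, x$trial_s, x$ramp_s, x$rest_range_s[1], x$rest_range_s[2]
  ))
  invisible(x)
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}
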