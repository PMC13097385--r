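#' Simulate a surface-EMG trace as a superposition of MUAP trains
#'
#' Physiological generative model: each motor unit whose recruitment
#' threshold lies below the instantaneous effort fires a renewal spike
#' train (Gamma inter-pulse intervals with mean `1 / mean_firing_rate` and
#' coefficient of variation `firing_cv`), and every spike deposits a
#' biphasic MUAP kernel (first derivative of a Gaussian) into the composite
#' trace. Gaussian measurement noise is added last. Zero effort therefore
#' yields pure noise, and with `noise_sd = 0` the output of a single unit
#' equals the convolution of its kernel with its spike impulse train.
#'
#' Fatigue within a contraction is modelled on a per-spike basis: across
#' each contiguous recruitment epoch the MUAP amplitude rises by the
#' fraction `fatigue` and the kernel duration widens by the fraction
#' `fatigue_mf` (widening shifts spectral content downward, i.e. median
#' frequency drifts down late in a hold).
#'
#' @param pool Motor-unit pool from [build_motor_unit_pool()].
#' @param effort_trace Numeric vector of effort values in \[0, 1\], one per
#'   sample.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param fatigue,fatigue_mf Per-contraction fractional amplitude rise /
#'   duration widening (default 0: stationary).
#' @return Numeric vector (mV) of `length(effort_trace)` samples, with
#'   attribute `"spike_times"`: a list (one integer vector per motor unit)
#'   of 1-based spike sample indices.
#' @export
simulate_semg <- function(pool, effort_trace, config = sim_config(), seed = 1L,
                          fatigue = 0, fatigue_mf = 0) {
  if (length(effort_trace) < 1L) abort("`effort_trace` must be non-empty")
  if (any(effort_trace < 0 | effort_trace > 1)) {
    abort("`effort_trace` values must lie in [0, 1]")
  }
  fs <- config$sampling_rate
  n <- length(effort_trace)
  set.seed(seed)

  signal <- numeric(n)
  spikes <- vector("list", nrow(pool))
  for (m in seq_len(nrow(pool))) {
    thr <- pool$recruitment_threshold[m]
    recruited <- effort_trace > thr
    if (!any(recruited)) {
      spikes[[m]] <- integer(0)
      next
    }
    runs <- rle_runs(recruited)
    mu_spikes <- integer(0)
    for (r in seq_len(nrow(runs))) {
      t0 <- runs$start[r]
      t1 <- runs$end[r] # inclusive sample indices of this recruitment epoch
      epoch_len <- t1 - t0 + 1L
      times <- sample_gamma_train(
        duration_s = epoch_len / fs,
        rate_hz = pool$mean_firing_rate[m],
        cv = config$firing_cv
      )
      if (!length(times)) next
      idx <- t0 + as.integer(round(times * fs))
      idx <- idx[idx >= t0 & idx <= t1]
      if (!length(idx)) next
      prog <- (idx - t0) / epoch_len # 0..1 progression through the epoch
      stationary <- fatigue == 0 && fatigue_mf == 0
      if (stationary) {
        kernels <- list(muap_kernel(pool$muap_duration[m], pool$muap_amplitude[m], fs))
        lev <- rep(1L, length(idx))
      } else {
        # fatigue progression quantized to 10 levels so kernels are reusable
        nlev <- 10L
        mid <- (seq_len(nlev) - 0.5) / nlev
        kernels <- lapply(mid, function(q) {
          muap_kernel(
            pool$muap_duration[m] * (1 + fatigue_mf * q),
            pool$muap_amplitude[m] * (1 + fatigue * q),
            fs
          )
        })
        lev <- pmin(floor(prog * nlev) + 1L, nlev)
      }
      for (j in seq_along(idx)) {
        k <- kernels[[lev[j]]]
        half <- (length(k) - 1L) %/% 2L
        lo <- idx[j] - half
        hi <- idx[j] + half
        klo <- max(1L, 1L - lo + 1L)
        khi <- length(k) - max(0L, hi - n)
        lo <- max(lo, 1L)
        hi <- min(hi, n)
        if (lo <= hi) signal[lo:hi] <- signal[lo:hi] + k[klo:khi]
      }
      mu_spikes <- c(mu_spikes, idx)
    }
    spikes[[m]] <- mu_spikes
  }
  if (config$noise_sd > 0) signal <- signal + rnorm(n, 0, config$noise_sd)
  attr(signal, "spike_times") <- spikes
  signal
}

# contiguous TRUE runs of a logical vector, as inclusive start/end indices
rle_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# renewal spike train on [0, duration_s): Gamma ISIs, mean 1/rate, given CV
sample_gamma_train <- function(duration_s, rate_hz, cv) {
  shape <- 1 / cv^2
  expected <- duration_s * rate_hz
  times <- numeric(0)
  t <- runif(1, 0, 1 / rate_hz) # random phase of the first spike
  while (t < duration_s) {
    times <- c(times, t)
    t <- t + rgamma(1, shape = shape, rate = shape * rate_hz)
    if (length(times) > 20 * expected + 100) break # guard against bad inputs
  }
  times
}

#' Simulate a piezoelectric strain channel for a grip effort profile
#'
#' The piezoelectric film responds to the *rate* of mechanical deformation:
#' the channel is modelled as a first-order rate-sensitive system
#' `tau * dy/dt + y = strain_gain * tau * dF/dt`, where `F` is grip force
#' (effort times the subject's grip strength, kg). A constant effort
#' therefore decays to zero output after a transient, while a steady force
#' ramp of slope `dF/dt` settles at the plateau
#' `strain_gain * tau * dF/dt` volts. Peak output scales linearly with
#' grip strength, so weaker (sarcopenic) subjects produce smaller strain
#' signals.
#'
#' @param effort_trace Numeric vector of effort values in \[0, 1\].
#' @param profile One-row data frame (or list) with at least
#'   `grip_strength` in kg (a `grip_kg` column is also accepted).
#' @param config A [sim_config()].
#' @param seed Integer seed for the additive noise.
#' @return Numeric vector (V) of strain-channel samples.
#' @export
simulate_strain <- function(effort_trace, profile, config = sim_config(), seed = 1L) {
  if (any(effort_trace < 0 | effort_trace > 1)) {
    abort("`effort_trace` values must lie in [0, 1]")
  }
  grip <- if ("grip_strength" %in% names(profile)) {
    profile$grip_strength
  } else {
    profile[["grip_kg"]]
  }
  if (is.null(grip) || !is.finite(grip) || grip <= 0) {
    abort("`profile` must carry a positive grip strength (kg)")
  }
  fs <- config$sampling_rate
  dt <- 1 / fs
  force <- effort_trace * grip
  alpha <- exp(-dt / config$strain_tau_s)
  # exact discretization of the first-order response to force increments
  dF <- c(0, diff(force))
  y <- as.numeric(stats::filter(config$strain_gain * dF, alpha, method = "recursive"))
  if (config$strain_noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, config$strain_noise_sd)
  }
  y
}

#' Trapezoidal effort profile of a full grip-test session
#'
#' Builds the per-sample effort trace and trial boundaries of a session:
#' a quiet lead-in, then `n_trials` maximal contractions of `trial_s`
#' seconds (linear ramp up, hold at 1, linear ramp down) separated by
#' rests drawn uniformly from `rest_range_s`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (controls the rest durations).
#' @return List with `effort` (numeric vector) and `trial_boundaries`
#'   (integer matrix, columns `start`/`end`, 0-based half-open sample
#'   intervals, one row per trial).
#' @export
session_effort <- function(config = sim_config(), seed = 1L) {
  fs <- config$sampling_rate
  set.seed(seed)
  rests <- runif(config$n_trials, config$rest_range_s[1], config$rest_range_s[2])
  trial_len <- as.integer(round(config$trial_s * fs))
  ramp_len <- as.integer(round(config$ramp_s * fs))
  hold_len <- trial_len - 2L * ramp_len
  trial_effort <- c(
    seq(0, 1, length.out = ramp_len + 1L)[-1L],
    rep(1, hold_len),
    rev(seq(0, 1, length.out = ramp_len + 1L)[-1L])
  )

  effort <- rep(0, as.integer(round(config$lead_in_s * fs)))
  bounds <- matrix(0L, nrow = config$n_trials, ncol = 2,
    dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(config$n_trials)) {
    bounds[i, 1] <- length(effort) # 0-based start
    effort <- c(effort, trial_effort)
    bounds[i, 2] <- length(effort) # 0-based half-open end
    effort <- c(effort, rep(0, as.integer(round(rests[i] * fs))))
  }
  list(effort = effort, trial_boundaries = bounds)
}

#' Generate one synchronized four-channel grip-test session
#'
#' Produces a full recording for one subject: brachioradialis (BR) and
#' flexor digitorum superficialis (FDS) sEMG channels driven by
#' independent motor-unit pools, and the two matching piezoelectric strain
#' channels, all sharing one trapezoidal effort trace with three maximal
#' contractions. Sarcopenic subjects get the sarcopenic pool (fewer,
#' larger, slower units), an overall composite-amplitude attenuation, and
#' a stronger within-contraction fatigue ramp; their weaker grip also
#' lowers the strain-channel output.
#'
#' Per-subject variability is injected as a +/-5% MUAP-duration jitter
#' and a +/-20% amplitude jitter applied to the whole pool.
#'
#' @param profile One-row data frame with `subject_id`, `group_label`
#'   (`"healthy"`/`"sarcopenia"`) and `grip_kg` (or `grip_strength`);
#'   an optional `phenotype` column (`"neural"`, `"mechanical"`,
#'   `"mixed"`) selects the sarcopenic presentation (default `"mixed"`).
#' @param config A [sim_config()].
#' @param seed Integer seed; the full session is a deterministic function
#'   of (`profile`, `config`, `seed`).
#' @return A `recording` object: list with `channels` (named list
#'   `br_semg`, `br_strain`, `fds_semg`, `fds_strain`), `sampling_rate`,
#'   `trial_boundaries` (0-based half-open matrix) and `subject_id`.
#' @export
generate_session <- function(profile, config = sim_config(), seed = 1L) {
  group <- match.arg(profile$group_label, c("healthy", "sarcopenia"))
  sess <- session_effort(config, seed = derive_seed(seed, 1L))

  # sarcopenic presentation: neural-dominant (full sEMG signature, normal
  # mechanics), mechanical-dominant (near-normal sEMG amplitude dynamics,
  # reduced deformation per force) or mixed. All sarcopenic pools share
  # the prolonged MUAP duration, so median frequency declines regardless.
  phen <- if (group != "sarcopenia") {
    "none"
  } else if ("phenotype" %in% names(profile)) {
    profile$phenotype[1]
  } else {
    "mixed"
  }
  electrical <- phen %in% c("neural", "mixed")
  mechanical <- phen %in% c("mechanical", "mixed")
  fat_group <- if (electrical) "sarcopenia" else "healthy"
  fat <- unname(config$fatigue_ramp[fat_group])
  fat_mf <- unname(config$fatigue_mf_drift[fat_group])
  atten <- if (group != "sarcopenia") {
    1
  } else if (electrical) {
    config$amplitude_attenuation_sarcopenic
  } else {
    config$mechanical_semg_attenuation
  }

  set.seed(derive_seed(seed, 2L))
  dur_jit <- runif(1, 0.95, 1.05)
  amp_jit <- runif(1, 0.8, 1.2)
  strain_jit <- runif(1, 0.85, 1.15)
  strain_atten <- if (mechanical) config$strain_attenuation_sarcopenic else 1

  semg_channel <- function(k) {
    pool <- build_motor_unit_pool(group, config, seed = derive_seed(seed, 10L + k))
    pool$muap_duration <- pool$muap_duration * dur_jit
    pool$muap_amplitude <- pool$muap_amplitude * amp_jit
    x <- simulate_semg(pool, sess$effort, config,
      seed = derive_seed(seed, 20L + k), fatigue = fat, fatigue_mf = fat_mf
    )
    as.numeric(x) * atten
  }

  strain_channel <- function(k, gain) {
    cfg_k <- config
    # contractile-quality attenuation and subject gain jitter act on the
    # mechanical response, not on the additive sensor noise
    cfg_k$strain_gain <- config$strain_gain * gain * strain_jit * strain_atten
    simulate_strain(sess$effort, profile, cfg_k, seed = derive_seed(seed, 30L + k))
  }

  channels <- list(
    br_semg = semg_channel(1L),
    br_strain = strain_channel(1L, 1),
    fds_semg = semg_channel(2L),
    fds_strain = strain_channel(2L, 0.9)
  )

  structure(
    list(
      channels = channels,
      sampling_rate = config$sampling_rate,
      trial_boundaries = sess$trial_boundaries,
      subject_id = as.character(profile$subject_id %||% "subject")
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording %s: %d channels x %d samples @ %g Hz, %d trials>\n",
    x$subject_id, length(x$channels), length(x$channels[[1]]),
    x$sampling_rate, nrow(x$trial_boundaries)
  ))
  invisible(x)
}

#' @describeIn generate_session Recording as a long-format tibble with a
#'   `time_s` column and one column per channel.
#' @param x A `recording`.
#' @param ... Unused.
#' @export
as_tibble.recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  tibble(
    time_s = (seq_len(n) - 1L) / x$sampling_rate,
    br_semg = x$channels$br_semg,
    br_strain = x$channels$br_strain,
    fds_semg = x$channels$fds_semg,
    fds_strain = x$channels$fds_strain
  )
}
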