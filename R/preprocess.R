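#' Min-max normalize a trace to \[-1, 1\]
#'
#' Centers the series on its mean and divides by the maximum absolute
#' deviation, so the output is bounded by 1 in magnitude and symmetric
#' around zero. Constant series map to all zeros. The transform is
#' idempotent on non-constant input.
#'
#' @param series Non-empty numeric vector.
#' @return Numeric vector of the same length.
#' @export
normalize_trace <- function(series) {
  if (!length(series)) abort("`series` must be non-empty")
  centered <- series - mean(series)
  peak <- max(abs(centered))
  if (peak == 0) {
    return(rep(0, length(series)))
  }
  centered / peak
}

# moving-RMS envelope; width in samples, edge values extended
moving_rms <- function(x, width) {
  width <- max(1L, as.integer(width))
  p <- as.numeric(stats::filter(x^2, rep(1 / width, width), sides = 2))
  # fill edge NAs with the nearest computed value
  ok <- which(!is.na(p))
  p[seq_len(ok[1] - 1L)] <- p[ok[1]]
  p[seq.int(ok[length(ok)] + 1L, length.out = length(p) - ok[length(ok)])] <- p[ok[length(ok)]]
  sqrt(pmax(p, 0))
}

#' Segment the active contraction window of each MVC trial
#'
#' Finds, inside each trial, the contiguous region where the moving-RMS
#' envelope exceeds `threshold_mult` times the rest baseline (the median
#' envelope level outside all trials). If the envelope never crosses the
#' threshold within a trial the hold phase (trial minus the effort ramps)
#' is returned as a fallback, with a warning.
#'
#' @param recording A `recording` (see [generate_session()]).
#' @param channel Channel name, e.g. `"br_semg"`.
#' @param threshold_mult Activity threshold as a multiple of the rest
#'   baseline envelope.
#' @param envelope_s Moving-RMS width in seconds.
#' @param ramp_s Assumed effort ramp duration (s), used only for the
#'   fallback hold-phase window.
#' @return Tibble with one row per trial: `trial`, `start`, `end` (0-based
#'   half-open sample interval), `t1`, `t2` (s), `n` (samples), `channel`,
#'   `fallback` (logical).
#' @export
segment_active_windows <- function(recording, channel = "br_semg",
                                   threshold_mult = 3, envelope_s = 0.1,
                                   ramp_s = 0.5) {
  x <- recording$channels[[channel]]
  if (is.null(x)) abort(sprintf("recording has no channel \"%s\"", channel))
  fs <- recording$sampling_rate
  tb <- recording$trial_boundaries
  env <- moving_rms(x, round(envelope_s * fs))

  in_trial <- rep(FALSE, length(x))
  for (i in seq_len(nrow(tb))) in_trial[(tb[i, 1] + 1L):tb[i, 2]] <- TRUE
  baseline <- median(env[!in_trial])
  thr <- max(threshold_mult * baseline, .Machine$double.eps)

  ramp_n <- as.integer(round(ramp_s * fs))
  out <- vector("list", nrow(tb))
  for (i in seq_len(nrow(tb))) {
    lo <- tb[i, 1] + 1L # 1-based inclusive
    hi <- tb[i, 2]
    active <- env[lo:hi] > thr
    if (any(active)) {
      runs <- rle_runs(active)
      r <- runs[which.max(runs$end - runs$start), ]
      start <- tb[i, 1] + r$start - 1L # back to 0-based
      end <- tb[i, 1] + r$end
      fallback <- FALSE
    } else {
      warn(sprintf("trial %d: no activity above threshold; using hold phase", i))
      start <- tb[i, 1] + ramp_n
      end <- tb[i, 2] - ramp_n
      fallback <- TRUE
    }
    out[[i]] <- tibble(
      trial = i, start = start, end = end,
      t1 = start / fs, t2 = end / fs, n = end - start,
      channel = channel, fallback = fallback
    )
  }
  list_rbind(out)
}

#' Extract the samples of a window from a recording
#'
#' @param recording A `recording`.
#' @param window One row of the tibble returned by
#'   [segment_active_windows()] (or any list with 0-based half-open
#'   `start`/`end` and a `channel`).
#' @return Numeric vector of samples.
#' @export
window_samples <- function(recording, window) {
  recording$channels[[window$channel]][(window$start + 1L):window$end]
}

#' Signal-to-noise ratio between an active and a rest window
#'
#' `SNR = 20 log10(RMS_signal / RMS_noise)` in dB.
#'
#' @param signal_window,noise_window Non-empty numeric vectors.
#' @return SNR in dB.
#' @export
compute_snr <- function(signal_window, noise_window) {
  if (!length(signal_window) || !length(noise_window)) {
    abort("both windows must be non-empty")
  }
  rn <- rms(noise_window)
  if (rn == 0) abort("noise RMS is zero; SNR undefined")
  20 * log10(rms(signal_window) / rn)
}

# Welch power spectral density: Hann-windowed segments, averaged one-sided
# periodograms. Returns frequency grid (Hz) and density (units^2/Hz).
welch_psd <- function(x, sampling_rate, seg_s = 1, overlap = 0.5) {
  n <- length(x)
  L <- min(n, max(8L, as.integer(round(seg_s * sampling_rate))))
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  wnorm <- sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    p <- Mod(fft(seg))^2 / (sampling_rate * wnorm)
    half <- p[seq_len(nf)]
    # fold negative frequencies into the one-sided density
    interior <- 2:(nf - 1L + (L %% 2L))
    half[interior] <- 2 * half[interior]
    acc <- acc + half
  }
  list(
    frequency = (seq_len(nf) - 1L) * sampling_rate / L,
    psd = acc / length(starts)
  )
}

#' Median frequency of a signal window
#'
#' Frequency at which the cumulative power of the window's Welch power
#' spectral density reaches half the total power, with linear
#' interpolation between frequency bins. Median frequency of sEMG tracks
#' muscle-fibre composition and fatigue: a shift toward slow fibres or a
#' fatiguing muscle moves it downward.
#'
#' @param window Numeric vector of at least 64 samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param seg_s,overlap Welch segment length (s) and fractional overlap.
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(window, sampling_rate, seg_s = 1, overlap = 0.5) {
  if (length(window) < 64L) abort("`window` must have at least 64 samples")
  spec <- welch_psd(window, sampling_rate, seg_s = seg_s, overlap = overlap)
  psd_median_frequency(spec$frequency, spec$psd)
}

# interpolated median of a sampled power density
psd_median_frequency <- function(frequency, psd) {
  total <- sum(psd)
  if (total <= 0) abort("window has zero power; median frequency undefined")
  cum <- cumsum(psd)
  half <- total / 2
  k <- which(cum >= half)[1]
  if (k == 1L) {
    return(frequency[1])
  }
  prev <- cum[k - 1L]
  frac <- (half - prev) / (cum[k] - prev)
  frequency[k - 1L] + frac * (frequency[k] - frequency[k - 1L])
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Hann-windowed STFT (via [signal::specgram()]) returning linear
#' magnitudes on a time x frequency grid. Useful for visualizing the
#' low-frequency energy concentration of sarcopenic sEMG.
#'
#' @param series Numeric vector.
#' @param sampling_rate Sampling rate, Hz.
#' @param window_s Analysis window length in seconds (`window_s *
#'   sampling_rate` must be at least 32 samples).
#' @param overlap Fractional window overlap in \[0, 1).
#' @return A `spectrogram` object: list with `time_bins` (s, window
#'   centers), `frequency_bins` (Hz) and `magnitude` (time x frequency
#'   matrix).
#' @export
stft_spectrogram <- function(series, sampling_rate, window_s = 0.5, overlap = 0.75) {
  L <- as.integer(round(window_s * sampling_rate))
  if (L < 32L) abort("`window_s * sampling_rate` must be at least 32 samples")
  if (length(series) < L) abort("`series` is shorter than one analysis window")
  sg <- signal::specgram(series,
    n = L, Fs = sampling_rate,
    window = signal::hanning(L), overlap = as.integer(round(overlap * L))
  )
  structure(
    list(
      time_bins = as.numeric(sg$t),
      frequency_bins = as.numeric(sg$f),
      magnitude = t(Mod(sg$S)) # rows = time frames, cols = frequencies
    ),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram: %d frames x %d frequencies (0-%g Hz)>\n",
    length(x$time_bins), length(x$frequency_bins), max(x$frequency_bins)
  ))
  invisible(x)
}

#' Spectral centroid of each spectrogram frame
#'
#' Power-weighted mean frequency per time frame; a summary of where
#' spectral energy concentrates.
#'
#' @param spectrogram A `spectrogram` from [stft_spectrogram()].
#' @return Numeric vector, one centroid (Hz) per frame.
#' @export
spectral_centroid <- function(spectrogram) {
  p <- spectrogram$magnitude^2
  as.numeric(p %*% spectrogram$frequency_bins) / pmax(rowSums(p), .Machine$double.xmin)
}

#' Optional 20-450 Hz band-pass for sEMG conditioning
#'
#' A 4th-order Butterworth band-pass applied forward-backward
#' (zero-phase). Off by default throughout the pipeline; when used, the
#' returned series carries attribute `"bandpassed" = TRUE` so downstream
#' reports can log that conditioning was applied.
#'
#' @param series Numeric vector.
#' @param sampling_rate Sampling rate, Hz.
#' @param band Two-element passband in Hz (upper edge below Nyquist).
#' @return Filtered numeric vector.
#' @export
bandpass_semg <- function(series, sampling_rate, band = c(20, 450)) {
  ny <- sampling_rate / 2
  if (band[2] >= ny) abort("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(4, band / ny, type = "pass")
  out <- as.numeric(signal::filtfilt(bf, series))
  attr(out, "bandpassed") <- TRUE
  out
}
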