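#' Continuous wavelet transform with an analytic Morlet wavelet
#'
#' FFT-based CWT using the analytic Morlet wavelet (centre frequency
#' `omega0`, default 6). Scales are laid out logarithmically between the
#' requested equivalent Fourier frequencies, using the standard Morlet
#' scale-to-frequency relation `s = (omega0 + sqrt(2 + omega0^2)) /
#' (4 * pi * f)`.
#'
#' @param x Numeric vector (at least 64 samples).
#' @param sampling_rate Sampling rate, Hz.
#' @param n_scales Number of scales (>= 4).
#' @param freq_range Two-element range of equivalent frequencies in Hz.
#' @param omega0 Morlet centre frequency (dimensionless).
#' @return List with `coefficients` (complex matrix, scales x time),
#'   `scales` (s) and `frequencies` (Hz, descending scale order).
#' @export
morlet_cwt <- function(x, sampling_rate, n_scales = 32,
                       freq_range = c(10, 450), omega0 = 6) {
  if (length(x) < 64L) abort("`x` must have at least 64 samples")
  if (n_scales < 4L) abort("`n_scales` must be at least 4")
  if (freq_range[2] > sampling_rate / 2) {
    freq_range[2] <- sampling_rate / 2
  }
  n <- length(x)
  dt <- 1 / sampling_rate
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_scales))
  conv <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi) # Fourier factor
  scales <- conv / freqs

  xf <- fft(x)
  omega <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * dt)
  coef <- matrix(0i, nrow = n_scales, ncol = n)
  for (k in seq_len(n_scales)) {
    s <- scales[k]
    # analytic Morlet daughter in the frequency domain (positive freqs only)
    psi <- ifelse(omega > 0,
      pi^(-0.25) * sqrt(2 * pi * s / dt) * exp(-((s * omega - omega0)^2) / 2),
      0
    )
    coef[k, ] <- fft(xf * psi, inverse = TRUE) / n
  }
  list(coefficients = coef, scales = scales, frequencies = freqs)
}

#' Shannon entropy of a scale-energy distribution
#'
#' Wavelet entropy in nats: `-sum(p * log(p))` with
#' `p_s = E_s / sum(E_s)`. Zero-energy scales contribute nothing; a
#' distribution concentrated on one scale has entropy 0 and a uniform
#' distribution over S scales has entropy `log(S)`.
#'
#' @param energies Non-negative per-scale energies with positive total.
#' @return Entropy in nats.
#' @export
wavelet_entropy <- function(energies) {
  if (any(energies < 0)) abort("energies must be non-negative")
  total <- sum(energies)
  if (total <= 0) abort("total energy is zero; wavelet entropy undefined")
  p <- energies / total
  p <- p[p > 0]
  -sum(p * log(p))
}
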