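test_that("normalize_trace scales symmetrically to [-1, 1]", {
  expect_equal(normalize_trace(c(-2, 0, 2)), c(-1, 0, 1))
  expect_equal(normalize_trace(c(5, 5, 5)), c(0, 0, 0))
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(50, mean = runif(1, -3, 3), sd = runif(1, 0.1, 5))
    y <- normalize_trace(x)
    expect_lte(max(abs(y)), 1)
    expect_equal(normalize_trace(y), y) # idempotent on non-constant input
  }
  expect_error(normalize_trace(numeric(0)), "non-empty")
})

test_that("active windows coincide with the effort plateau on noise-free sessions", {
  cfg <- sim_config(noise_sd = 0.0005, strain_noise_sd = 0.0005)
  rec <- generate_session(fixture_profile(), cfg, seed = 41)
  wins <- segment_active_windows(rec, "br_semg")
  expect_equal(nrow(wins), 3L)
  tb <- rec$trial_boundaries
  ramp_n <- cfg$ramp_s * cfg$sampling_rate
  for (i in 1:3) {
    # window within the trial, covering the hold to within a ramp's width
    expect_gte(wins$start[i], tb[i, 1])
    expect_lte(wins$end[i], tb[i, 2])
    expect_lte(wins$start[i], tb[i, 1] + ramp_n)
    expect_gte(wins$end[i], tb[i, 2] - ramp_n)
  }
})

test_that("an all-noise recording falls back to hold-phase windows with warnings", {
  cfg <- sim_config()
  rec <- generate_session(fixture_profile(), cfg, seed = 43)
  rec$channels$br_semg <- rnorm(length(rec$channels$br_semg), 0, 0.01)
  expect_warning(
    wins <- segment_active_windows(rec, "br_semg"),
    "no activity"
  )
  expect_equal(nrow(wins), 3L)
  expect_true(all(wins$fallback))
})

test_that("window length is monotonically non-increasing in the activity threshold", {
  rec <- generate_session(fixture_profile(), sim_config(), seed = 44)
  lens <- sapply(c(1.5, 3, 6, 12, 24), function(th) {
    sum(segment_active_windows(rec, "br_semg", threshold_mult = th)$n)
  })
  expect_false(is.unsorted(rev(lens)))
})

test_that("SNR matches its closed form and is gain-invariant", {
  noise <- rnorm(1000, 0, 0.5)
  expect_equal(compute_snr(noise * 10, noise), 20)
  expect_equal(compute_snr(noise, noise), 0)
  sig <- rnorm(500, 0, 3)
  expect_equal(compute_snr(sig, noise), compute_snr(sig * 7.3, noise * 7.3))
  expect_error(compute_snr(sig, rep(0, 100)), "zero")
})

test_that("median frequency of a pure 50 Hz sine is 50 Hz within one bin", {
  t <- seq(0, 5, by = 1e-3)[-1]
  x <- sin(2 * pi * 50 * t)
  expect_equal(median_frequency(x, 1000), 50, tolerance = 1) # 1 Hz bins
  expect_error(median_frequency(rep(0, 1000), 1000), "zero power")
  expect_error(median_frequency(rnorm(32), 1000), "64")
})

test_that("median frequency matches the cumulative-periodogram oracle", {
  # single-segment windows so Welch reduces to one Hann periodogram,
  # recomputed independently by a naive DFT oracle
  set.seed(2024)
  for (i in 1:50) {
    x <- as.numeric(arima.sim(list(ar = runif(1, -0.6, 0.6)), 1000)) +
      sin(2 * pi * runif(1, 20, 200) * seq_len(1000) / 1000)
    mf <- median_frequency(x, 1000, seg_s = 1)
    expect_equal(mf, oracle_mf_periodogram(x, 1000), tolerance = 1.0001)
  }
})

test_that("two-tone median frequency sits at the oracle's power-balance point", {
  t <- seq_len(5000) / 1000
  x <- sin(2 * pi * 40 * t) + sin(2 * pi * 160 * t)
  mf <- median_frequency(x, 1000, seg_s = 5)
  expect_gt(mf, 40)
  expect_lt(mf, 160)
  expect_equal(mf, oracle_mf_periodogram(x, 1000), tolerance = 0.21)
})

test_that("white-noise median frequency concentrates near half Nyquist", {
  set.seed(7)
  mfs <- replicate(100, median_frequency(rnorm(1000), 1000))
  expect_equal(mean(mfs), 250, tolerance = 0.03 * 250)
})

test_that("STFT spectrogram tracks a chirp and zeroes out on zero input", {
  fs <- 1000
  t <- seq_len(4000) / fs
  # linear chirp 20 -> 150 Hz
  x <- sin(2 * pi * (20 * t + (150 - 20) / (2 * max(t)) * t^2))
  sg <- stft_spectrogram(x, fs, window_s = 0.5, overlap = 0.75)
  peak <- sg$frequency_bins[apply(sg$magnitude, 1, which.max)]
  expect_false(is.unsorted(peak))
  expect_lte(max(sg$frequency_bins), fs / 2)
  expect_true(all(sg$magnitude >= 0))

  sg0 <- stft_spectrogram(rep(0, 2000), fs)
  expect_equal(max(sg0$magnitude), 0)
  expect_error(stft_spectrogram(rnorm(100), fs, window_s = 0.5), "shorter")
  expect_error(stft_spectrogram(rnorm(100), fs, window_s = 0.02), "at least 32")
})

test_that("spectrogram frames match a directly computed windowed FFT", {
  set.seed(9)
  x <- rnorm(1024)
  L <- 128
  sg <- stft_spectrogram(x, 1000, window_s = L / 1000, overlap = 0)
  w <- signal::hanning(L)
  manual <- Mod(fft(x[1:L] * w))
  frame1 <- sg$magnitude[1, ]
  expect_equal(as.numeric(frame1), as.numeric(manual)[seq_along(frame1)],
    tolerance = 1e-8
  )
})

test_that("optional band-pass keeps in-band tones and flags its application", {
  fs <- 1000
  t <- seq_len(2000) / fs
  x <- sin(2 * pi * 100 * t) + sin(2 * pi * 5 * t)
  y <- bandpass_semg(x, fs)
  expect_true(attr(y, "bandpassed"))
  # the 5 Hz component is attenuated, the 100 Hz one preserved
  mf <- median_frequency(as.numeric(y), fs)
  expect_gt(mf, 80)
  expect_error(bandpass_semg(x, fs, band = c(20, 600)), "Nyquist")
})
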