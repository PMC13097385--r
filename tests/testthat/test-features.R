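test_that("Hudgins features reproduce hand-computed values", {
  f <- hudgins_features(c(3, -4), sampling_rate = 1000, epsilon = 0)
  expect_equal(f$rms, sqrt((9 + 16) / 2))
  expect_equal(f$mav, 3.5)
  expect_equal(f$iemg, 0.007)
  expect_equal(f$wl, 7)
  expect_equal(f$zc, 1L)
  expect_equal(f$ssc, 0L)

  const <- hudgins_features(rep(2.5, 10), 1000, epsilon = 0)
  expect_equal(const$rms, 2.5)
  expect_equal(const$mav, 2.5)
  expect_equal(const$wl, 0)
  expect_equal(const$zc, 0L)
  expect_equal(const$ssc, 0L)

  alt <- hudgins_features(c(1, -1, 1, -1), 1000, epsilon = 0)
  expect_equal(alt$zc, 3L)
  expect_equal(alt$ssc, 2L)
  expect_equal(alt$wl, 6)

  expect_error(hudgins_features(3, 1000), "at least 2")
  expect_error(hudgins_features(c(1, 2), 1000, epsilon = -1), "non-negative")
})

test_that("Hudgins features match the naive-loop oracle on random windows", {
  set.seed(321)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    x <- if (i %% 2 == 0) {
      as.numeric(sample(-10:10, n, replace = TRUE)) # integer inputs: exact
    } else {
      rnorm(n, sd = runif(1, 0.1, 10))
    }
    eps <- if (i %% 3 == 0) 0 else 0.01 * sqrt(mean(x^2))
    got <- hudgins_features(x, 1000, epsilon = eps)
    want <- oracle_hudgins(x, 1000, eps)
    tol <- if (i %% 2 == 0) 0 else 1e-12
    expect_equal(got$rms, want$rms, tolerance = tol)
    expect_equal(got$mav, want$mav, tolerance = tol)
    expect_equal(got$iemg, want$iemg, tolerance = tol)
    expect_equal(got$wl, want$wl, tolerance = tol)
    expect_identical(got$zc, as.integer(want$zc))
    expect_identical(got$ssc, as.integer(want$ssc))
  }
})

test_that("RMS dominates MAV on any window (power-mean inequality)", {
  set.seed(5)
  for (i in 1:25) {
    f <- hudgins_features(rnorm(100, sd = runif(1, 0.1, 5)), 1000)
    expect_gte(f$rms, f$mav)
  }
})

test_that("feature scale equivariance and invariance hold under gain", {
  set.seed(6)
  x <- rnorm(500)
  g <- 7.3
  eps <- 0.01 * sqrt(mean(x^2))
  a <- hudgins_features(x, 1000, epsilon = eps)
  b <- hudgins_features(g * x, 1000, epsilon = g * eps)
  expect_equal(b$rms, g * a$rms)
  expect_equal(b$mav, g * a$mav)
  expect_equal(b$wl, g * a$wl)
  expect_identical(b$zc, a$zc)
  expect_identical(b$ssc, a$ssc)
  ca <- cwt_features(x, 1000)
  cb <- cwt_features(g * x, 1000)
  expect_equal(cb$we, ca$we) # entropy of a normalized distribution
  expect_equal(cb$cwt_power, g^2 * ca$cwt_power)
})

test_that("wavelet features behave on degenerate and structured inputs", {
  expect_equal(cwt_features(rep(0, 256), 1000)$cwt_power, 0)
  expect_equal(wavelet_entropy(rep(3, 32)), log(32))
  expect_equal(wavelet_entropy(c(0, 5, 0)), 0)
  expect_error(wavelet_entropy(c(0, 0)), "zero")
  expect_error(wavelet_entropy(c(-1, 2)), "non-negative")
  expect_error(morlet_cwt(rnorm(32), 1000), "64")
  expect_error(morlet_cwt(rnorm(128), 1000, n_scales = 2), "at least 4")
})

test_that("narrowband signals have lower wavelet entropy than broadband noise", {
  set.seed(11)
  t <- seq_len(1000) / 1000
  for (i in 1:20) {
    tone <- sin(2 * pi * runif(1, 40, 200) * t)
    noise <- rnorm(1000)
    expect_lt(cwt_features(tone, 1000)$we, cwt_features(noise, 1000)$we)
  }
})

test_that("the engineering stage emits exactly nine named features", {
  expect_length(feature_names(), 9L)
  x <- rnorm(256)
  row <- dplyr::bind_cols(hudgins_features(x, 1000), cwt_features(x, 1000))
  expect_named(row, feature_names())
  # six time-domain + three time-frequency
  expect_length(intersect(names(row), c("rms", "mav", "iemg", "wl", "zc", "ssc")), 6L)
  expect_length(intersect(names(row), c("cwt_power", "cwt_kurtosis", "we")), 3L)
})

test_that("MVC normalization divides by the three-trial mean", {
  tab <- tibble::tibble(
    subject_id = "A", channel = "br_semg", trial = 1:3,
    rms = c(2, 3, 4)
  )
  out <- mvc_normalize(tab)
  expect_equal(out$rms, c(2, 3, 4) / 3)
  expect_true(all(out$normalized))

  same <- mvc_normalize(tibble::tibble(
    subject_id = "A", channel = "br_semg", trial = 1:3, rms = c(5, 5, 5)
  ))
  expect_equal(same$rms, c(1, 1, 1))

  expect_error(
    mvc_normalize(tibble::tibble(
      subject_id = "A", channel = "br_semg", trial = 1:2, rms = c(1, 2)
    )),
    "exactly 3"
  )
  expect_error(
    mvc_normalize(tibble::tibble(
      subject_id = "A", channel = "br_semg", trial = 1:3, rms = c(0, 0, 0)
    )),
    "zero MVC trial mean.*\"rms\".*A"
  )
})

test_that("normalized trial-level means equal 1 per subject, channel and feature", {
  ft <- fixture_features()
  trial_rows <- ft[ft$kind == "trial", ]
  means <- trial_rows |>
    dplyr::group_by(subject_id, channel) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feature_names()), mean),
      .groups = "drop"
    )
  for (f in feature_names()) {
    expect_equal(means[[f]], rep(1, nrow(means)), tolerance = 1e-12)
  }
})

test_that("group comparison reports direction and corrected p-values", {
  ft <- fixture_features()
  res <- group_compare(ft)
  expect_equal(nrow(res), 9L)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  amp <- res[res$feature %in% c("rms", "mav", "iemg", "wl"), ]
  expect_true(all(amp$direction == "sarcopenia"))
  expect_error(
    group_compare(dplyr::mutate(ft, group_label = "healthy")),
    "two groups"
  )
})

test_that("group comparison type-I error is near nominal under the null", {
  set.seed(77)
  reject <- replicate(300, {
    tab <- tibble::tibble(subject_id = sprintf("S%02d", 1:20))
    for (f in feature_names()) tab[[f]] <- rnorm(20)
    tab$group_label <- rep(c("a", "b"), each = 10)
    mean(group_compare(tab)$p_value < 0.05)
  })
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.08)
})
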