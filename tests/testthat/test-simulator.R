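test_that("motor-unit pools follow the size principle and group scaling", {
  cfg <- sim_config()
  pool <- build_motor_unit_pool("healthy", cfg, seed = 1)
  expect_equal(nrow(pool), cfg$n_motor_units_healthy)
  expect_false(is.unsorted(pool$recruitment_threshold, strictly = TRUE))
  expect_false(is.unsorted(pool$muap_amplitude, strictly = TRUE))
  expect_true(all(pool$recruitment_threshold >= 0 & pool$recruitment_threshold < 1))
  expect_true(all(pool$muap_duration > 0) && all(pool$mean_firing_rate > 0))

  # matched pools (same size, same seed): sarcopenic durations are a pure
  # rescaling of the healthy ones
  cfg_eq <- sim_config(n_motor_units_sarcopenic = cfg$n_motor_units_healthy)
  h <- build_motor_unit_pool("healthy", cfg_eq, seed = 1)
  s <- build_motor_unit_pool("sarcopenia", cfg_eq, seed = 1)
  expect_equal(s$muap_duration, h$muap_duration * cfg$duration_scale_sarcopenic)

  one <- build_motor_unit_pool("healthy", sim_config(n_motor_units_healthy = 1), seed = 7)
  expect_equal(nrow(one), 1L)
  expect_lt(one$recruitment_threshold, 1)

  expect_error(sim_config(n_motor_units_healthy = 0), ">= 1")
})

test_that("zero effort with zero noise produces an all-zero sEMG trace", {
  cfg <- sim_config(noise_sd = 0)
  pool <- build_motor_unit_pool("healthy", cfg, seed = 2)
  x <- simulate_semg(pool, rep(0, 2000), cfg, seed = 3)
  expect_equal(as.numeric(x), rep(0, 2000))
  expect_error(simulate_semg(pool, c(0.5, 1.2), cfg), "\\[0, 1\\]")
})

test_that("single-unit noise-free sEMG equals kernel convolved with its spike train", {
  cfg <- sim_config(noise_sd = 0, n_motor_units_healthy = 1)
  pool <- build_motor_unit_pool("healthy", cfg, seed = 5)
  n <- 3000
  x <- simulate_semg(pool, rep(1, n), cfg, seed = 6)
  spikes <- attr(x, "spike_times")[[1]]
  expect_gt(length(spikes), 10)

  # brute-force oracle: place the kernel at each logged spike index
  sigma <- pool$muap_duration / 6 / 1000
  half <- ceiling(3 * sigma * cfg$sampling_rate)
  u <- (-half:half) / cfg$sampling_rate
  kern <- pool$muap_amplitude * -(u / sigma) * exp(-u^2 / (2 * sigma^2)) * exp(0.5)
  expected <- numeric(n)
  for (s in spikes) {
    for (j in seq_along(kern)) {
      t <- s + j - half - 1
      if (t >= 1 && t <= n) expected[t] <- expected[t] + kern[j]
    }
  }
  expect_equal(as.numeric(x), expected, tolerance = 1e-12)
})

test_that("doubling MUAP amplitudes doubles the noise-free composite RMS", {
  cfg <- sim_config(noise_sd = 0)
  pool <- build_motor_unit_pool("healthy", cfg, seed = 8)
  x1 <- simulate_semg(pool, rep(1, 2000), cfg, seed = 9)
  pool2 <- pool
  pool2$muap_amplitude <- 2 * pool2$muap_amplitude
  x2 <- simulate_semg(pool2, rep(1, 2000), cfg, seed = 9)
  expect_equal(sqrt(mean(x2^2)), 2 * sqrt(mean(x1^2)), tolerance = 1e-12)
})

test_that("median frequency decreases monotonically with MUAP duration scale", {
  scales <- c(1, 1.25, 1.5, 1.8)
  mf <- sapply(scales, function(sc) {
    cfg <- sim_config(
      noise_sd = 0, n_motor_units_healthy = 40,
      muap_duration_ms = 10 * sc
    )
    mean(sapply(1:8, function(s) {
      pool <- build_motor_unit_pool("healthy", cfg, seed = s)
      x <- simulate_semg(pool, rep(1, 3000), cfg, seed = 100 + s)
      median_frequency(as.numeric(x), cfg$sampling_rate)
    }))
  })
  expect_false(is.unsorted(rev(mf)))
})

test_that("strain channel shows rate-sensitive first-order behaviour", {
  cfg <- sim_config(strain_noise_sd = 0)
  prof <- fixture_profile(grip = 30)

  # constant effort after a quick step: output decays to ~0 (rate-sensitive)
  y_const <- simulate_strain(c(seq(0, 1, length.out = 200), rep(1, 1800)), prof, cfg)
  expect_gt(max(abs(y_const)), 0)
  expect_lt(max(abs(y_const[1500:2000])), 1e-3 * max(abs(y_const)))

  # steady ramp: plateau matches the analytic first-order response
  fs <- cfg$sampling_rate
  ramp <- seq(0, 1, length.out = fs)[1:fs]
  y_ramp <- simulate_strain(ramp, prof, cfg)
  slope_kg_s <- 30 / 1 # grip * (effort per second)
  plateau <- cfg$strain_gain * cfg$strain_tau_s * slope_kg_s
  expect_equal(y_ramp[fs], plateau * (1 - exp(-1 / cfg$strain_tau_s)),
    tolerance = 0.02
  )

  # linear in grip strength: 30 kg vs 15 kg gives a 2:1 peak ratio
  y_half <- simulate_strain(ramp, fixture_profile(grip = 15), cfg)
  expect_equal(max(abs(y_ramp)) / max(abs(y_half)), 2, tolerance = 1e-9)

  expect_error(simulate_strain(ramp, list(grip_strength = -3), cfg), "positive")
})

test_that("sessions have exactly 3 MVC trials of 5000 samples at 1000 Hz", {
  cfg <- sim_config()
  rec <- generate_session(fixture_profile(), cfg, seed = 11)
  tb <- rec$trial_boundaries
  expect_equal(nrow(tb), 3L)
  expect_equal(unname(tb[, 2] - tb[, 1]), rep(5000L, 3))
  expect_equal(rec$sampling_rate, 1000)
  expect_named(rec$channels, c("br_semg", "br_strain", "fds_semg", "fds_strain"))
  expect_equal(length(unique(lengths(rec$channels))), 1L)
  # rests between trials in [4, 6] s
  gaps <- (tb[-1, 1] - tb[-3, 2]) / cfg$sampling_rate
  expect_true(all(gaps >= 4 & gaps <= 6))
})

test_that("sessions are bit-identical under a fixed seed", {
  prof <- fixture_profile("sarcopenia", grip = 20)
  r1 <- generate_session(prof, sim_config(), seed = 21)
  r2 <- generate_session(prof, sim_config(), seed = 21)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$trial_boundaries, r2$trial_boundaries)
})

test_that("sarcopenic sessions have lower raw sEMG envelope amplitude", {
  cfg <- sim_config()
  amp <- function(group, seed) {
    prof <- fixture_profile(group, grip = if (group == "healthy") 36 else 22)
    rec <- generate_session(prof, cfg, seed = seed)
    tb <- rec$trial_boundaries
    mean(sapply(1:3, function(i) {
      sd(rec$channels$br_semg[(tb[i, 1] + 1):tb[i, 2]])
    }))
  }
  seeds <- 1:20
  h <- sapply(seeds, function(s) amp("healthy", s))
  s <- sapply(seeds, function(s) amp("sarcopenia", 1000 + s))
  expect_lt(mean(s), mean(h))
})

test_that("generated cohorts are label-consistent and balanced as requested", {
  co <- fixture_cohort()
  expect_equal(nrow(co), 6L)
  expect_equal(sum(co$group_label == "sarcopenia"), 3L)
  expect_true(all(co$age >= 60))
  scr <- classify_awgs(co)
  expect_equal(scr$classification, co$group_label)

  two <- generate_cohort(n_subjects = 2, prevalence = 0.5, sim_config(), seed = 9)
  expect_setequal(two$group_label, c("healthy", "sarcopenia"))

  expect_error(generate_cohort(n_subjects = 1), ">= 2")
  expect_error(generate_cohort(n_subjects = 10, prevalence = 1.2), "prevalence")
})

test_that("cohorts are identical under identical (config, seed)", {
  a <- generate_cohort(n_subjects = 2, prevalence = 0.5, sim_config(), seed = 17)
  b <- generate_cohort(n_subjects = 2, prevalence = 0.5, sim_config(), seed = 17)
  expect_identical(a$recording[[1]]$channels, b$recording[[1]]$channels)
  expect_identical(a$grip_kg, b$grip_kg)
})

test_that("cohort CSV + manifest round-trips through write_cohort/read_cohort", {
  co <- generate_cohort(n_subjects = 2, prevalence = 0.5, sim_config(), seed = 33)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(back$subject_id, co$subject_id)
  expect_equal(back$group_label, co$group_label)
  expect_equal(back$recording[[1]]$trial_boundaries, co$recording[[1]]$trial_boundaries)
  expect_equal(back$recording[[1]]$channels$br_semg,
    co$recording[[1]]$channels$br_semg,
    tolerance = 1e-6
  )
})
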