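# cached fixtures, generated in code once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture_cache <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# small cohort shared by the cheap unit tests
fixture_cohort <- function() {
  fixture_cache("cohort6", function() {
    generate_cohort(n_subjects = 6, prevalence = 0.5, sim_config(), seed = 301)
  })
}

fixture_features <- function() {
  fixture_cache("features6", function() {
    mvc_normalize(extract_features(fixture_cohort()))
  })
}

# study-scale cohort shared by the acceptance checks
fixture_cohort75 <- function(seed = 42) {
  fixture_cache(paste0("cohort75_", seed), function() {
    generate_cohort(n_subjects = 75, prevalence = 0.4, sim_config(), seed = seed)
  })
}

fixture_features75 <- function(seed = 42) {
  fixture_cache(paste0("features75_", seed), function() {
    mvc_normalize(extract_features(fixture_cohort75(seed)))
  })
}

fixture_profile <- function(group = "healthy", grip = 36) {
  tibble::tibble(
    subject_id = "T1", sex = "male", age = 70, grip_kg = grip,
    grip_strength = grip, smi = if (group == "healthy") 7.8 else 6.3,
    chair_stand_s = if (group == "healthy") 9 else 14, group_label = group
  )
}

# tiny dataset for model unit tests: random windows, one informative
# engineered feature
fixture_toy_dataset <- function(n = 24, steps = 64, channels = 2, seed = 99,
                                informative = "feature") {
  set.seed(seed)
  label <- rep(c("healthy", "sarcopenia"), length.out = n)
  windows <- lapply(seq_len(n), function(i) {
    base <- matrix(rnorm(steps * channels, sd = 0.3), steps, channels)
    if (informative == "window" && label[i] == "sarcopenia") base + 1 else base
  })
  features <- matrix(rnorm(n * 9, sd = 0.2), n, 9)
  if (informative == "feature") {
    features[, 1] <- ifelse(label == "sarcopenia", 1, -1) + rnorm(n, sd = 0.05)
  }
  structure(
    list(
      windows = windows,
      features = features,
      demo = cbind(sex = rep(0:1, length.out = n), age = rnorm(n, 70, 5),
        grip = rnorm(n, 30, 5)),
      label = factor(label, levels = c("healthy", "sarcopenia")),
      subject_id = sprintf("T%02d", seq_len(n)),
      trial = rep(1L, n),
      channels = paste0("ch", seq_len(channels))
    ),
    class = "fusion_dataset"
  )
}

toy_config <- function(...) {
  defaults <- list(
    conv_filters = c(4, 8), conv_kernel = 5, pool_size = 2,
    lstm_hidden = 8, mapping_channels = 4, dense_hidden = 8,
    dropout = 0, epochs = 10, batch_size = 8, learning_rate = 5e-3,
    downsample = 1, lstm_input_pool = 2
  )
  do.call(fusion_config, utils::modifyList(defaults, list(...)))
}
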