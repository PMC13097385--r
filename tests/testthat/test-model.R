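test_that("the fusion network honours its shape contract", {
  ds <- fixture_toy_dataset()
  cfg <- toy_config(epochs = 1)
  m <- train_fusion(ds, cfg)
  pr <- predict_proba(m, ds)
  expect_equal(dim(pr), c(24L, 2L))
  expect_equal(colnames(pr), c("healthy", "sarcopenia"))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(rowSums(pr), rep(1, 24), tolerance = 1e-6)
  expect_equal(nrow(m$history), 1L)

  # LSTM temporal-stream state dimension follows the config (64 by default)
  expect_equal(fusion_config()$lstm_hidden, 64L)
  expect_equal(ncol(m$params$Wh), 4L * cfg$lstm_hidden)

  bad <- fixture_toy_dataset(steps = 32)
  expect_error(predict_proba(m, bad), "input spec")
})

test_that("analytic gradients agree with finite differences", {
  ds <- fixture_toy_dataset(n = 2, steps = 32, seed = 5)
  cfg <- toy_config()
  set.seed(1)
  spec <- list(
    steps = 32L, channels = 2L, n_features = 9L, n_demo = 3L
  )
  params <- sarcscreen:::init_params("cnn_lstm", cfg, spec)
  X <- ds$windows[[1]]
  fv <- ds$features[1, ]
  dv <- ds$demo[1, ]
  fwd <- sarcscreen:::net_fwd("cnn_lstm", params, X, fv, dv, cfg)
  g <- sarcscreen:::net_bwd("cnn_lstm", params, fwd, 2L, X, fv, dv, cfg)
  loss_at <- function(p) {
    -log(sarcscreen:::net_fwd("cnn_lstm", p, X, fv, dv, cfg)$probs[2])
  }
  h <- 1e-5
  for (nm in c("W1", "W2", "Wx", "Wh", "Wf", "Wd", "Wz", "Wo", "bl", "bo")) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (k in idx) {
      p2 <- params
      p2[[nm]][k] <- p2[[nm]][k] + h
      num <- (loss_at(p2) - loss_at(params)) / h
      expect_equal(g[[nm]][k], num, tolerance = 5e-3)
    }
  }
})

test_that("training is deterministic and learns a separable feature rule", {
  ds <- fixture_toy_dataset(informative = "feature")
  cfg <- toy_config(epochs = 50)
  m1 <- train_fusion(ds, cfg)
  expect_equal(max(m1$history$accuracy), 1)

  m2 <- train_fusion(ds, cfg)
  expect_identical(m1$params, m2$params) # hash-equal weights

  # smoothed loss decreases on the separable problem
  sm <- stats::filter(m1$history$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
})

test_that("label-flipped retraining flips held-out predictions", {
  ds <- fixture_toy_dataset(informative = "feature", n = 20)
  train_idx <- 1:16
  test_idx <- 17:20
  cfg <- toy_config(epochs = 40)
  m <- train_fusion(dataset_subset(ds, train_idx), cfg)
  flipped <- ds
  flipped$label <- factor(
    ifelse(ds$label == "healthy", "sarcopenia", "healthy"),
    levels = levels(ds$label)
  )
  mf <- train_fusion(dataset_subset(flipped, train_idx), cfg)
  p1 <- predict_proba(m, dataset_subset(ds, test_idx))
  p2 <- predict_proba(mf, dataset_subset(ds, test_idx))
  expect_true(all(max.col(p1) != max.col(p2)))
})

test_that("prediction is pure: duplicated samples give identical outputs", {
  ds <- fixture_toy_dataset(n = 8)
  m <- train_fusion(ds, toy_config(epochs = 2))
  dup <- dataset_subset(ds, c(1L, 1L))
  pr <- predict_proba(m, dup)
  expect_identical(pr[1, ], pr[2, ])
})

test_that("baselines train on their prescribed inputs and share the interface", {
  ds <- fixture_toy_dataset(informative = "feature", n = 24)
  rf <- train_baseline("rf", ds, seed = 3)
  pr <- predict_proba(rf, ds)
  expect_equal(colnames(pr), c("healthy", "sarcopenia"))
  expect_equal(mean(colnames(pr)[max.col(pr)] == as.character(ds$label)), 1)

  svm <- train_baseline("svm", ds, seed = 3)
  ps <- predict_proba(svm, ds)
  expect_equal(unname(rowSums(ps)), rep(1, 24), tolerance = 1e-6)

  for (kind in c("cnn", "lstm")) {
    net <- train_baseline(kind, ds, seed = 3, config = toy_config(epochs = 2))
    pn <- predict_proba(net, ds)
    expect_equal(rowSums(pn), rep(1, 24), tolerance = 1e-6)
  }
  expect_error(train_baseline("mlp", ds), "unknown")
})

test_that("a 1-D SVM places its decision boundary at the margin midpoint", {
  # two tight 1-D clusters: the separating threshold is the midpoint of
  # the closest pair, here (1 + 3) / 2 = 2
  x <- matrix(c(0.8, 0.9, 1.0, 3.0, 3.1, 3.2), ncol = 1)
  y <- factor(rep(c("healthy", "sarcopenia"), each = 3),
    levels = c("healthy", "sarcopenia")
  )
  fit <- e1071::svm(x, y, kernel = "linear", cost = 1e4, scale = FALSE)
  lo <- predict(fit, matrix(1.95))
  hi <- predict(fit, matrix(2.05))
  expect_equal(as.character(lo), "healthy")
  expect_equal(as.character(hi), "sarcopenia")
})

test_that("the model trains with any stream-A channel subset (ablation contract)", {
  co <- fixture_cohort()
  ft <- fixture_features()
  cfg <- fusion_config(
    conv_filters = c(4, 8), lstm_hidden = 8, mapping_channels = 4,
    dense_hidden = 8, dropout = 0, epochs = 1, learning_rate = 1e-3
  )
  for (mod in c("both", "semg", "strain")) {
    ds <- build_dataset(co, ft, modality = mod)
    expect_equal(ncol(ds$windows[[1]]), if (mod == "both") 4L else 2L)
    m <- train_fusion(ds, cfg)
    pr <- predict_proba(m, ds)
    expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
  }
})
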