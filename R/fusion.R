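#' Configuration of the CNN-LSTM fusion classifier
#'
#' Hyperparameters of the three-stream network: a spatial stream (two
#' ReLU convolution blocks with max pooling over the raw multi-channel
#' window, feeding an LSTM with `lstm_hidden` units), a feature stream
#' (the nine engineered features lifted by a length-1 convolution, i.e. an
#' affine map, to `mapping_channels`) and a demographics stream (sex, age,
#' grip strength, lifted the same way). The three streams are
#' concatenated, passed through a dense ReLU layer with dropout, and
#' classified by a softmax over \{healthy, sarcopenia\}.
#'
#' @param conv_filters Two filter counts, one per convolution block.
#' @param conv_kernel Convolution kernel length (samples).
#' @param pool_size Max-pooling factor after each block.
#' @param lstm_hidden LSTM hidden units.
#' @param mapping_channels Width of the affine dimensional mapping applied
#'   to the feature and demographics streams.
#' @param dense_hidden Width of the post-concatenation dense layer.
#' @param dropout Dropout fraction on the dense layer during training.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param downsample Integer block-mean decimation factor applied to raw
#'   windows before the network (5000-sample trials at factor 20 become
#'   250-step sequences).
#' @param lstm_input_pool Extra average-pooling factor applied to raw
#'   windows for the LSTM-only baseline.
#' @param use_features,use_demo Stream ablation switches.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A list of class `"fusion_config"`.
#' @export
fusion_config <- function(conv_filters = c(32, 64), conv_kernel = 7,
                          pool_size = 4, lstm_hidden = 64,
                          mapping_channels = 16, dense_hidden = 32,
                          dropout = 0.3, epochs = 100, batch_size = 16,
                          learning_rate = 1e-3, downsample = 20,
                          lstm_input_pool = 8,
                          use_features = TRUE, use_demo = TRUE, seed = 1L) {
  if (length(conv_filters) != 2L) abort("`conv_filters` must give 2 blocks")
  if (lstm_hidden < 1L) abort("`lstm_hidden` must be >= 1")
  structure(
    list(
      conv_filters = as.integer(conv_filters),
      conv_kernel = as.integer(conv_kernel),
      pool_size = as.integer(pool_size),
      lstm_hidden = as.integer(lstm_hidden),
      mapping_channels = as.integer(mapping_channels),
      dense_hidden = as.integer(dense_hidden),
      dropout = dropout, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      downsample = as.integer(downsample),
      lstm_input_pool = as.integer(lstm_input_pool),
      use_features = isTRUE(use_features), use_demo = isTRUE(use_demo),
      seed = as.integer(seed)
    ),
    class = "fusion_config"
  )
}

# block-mean decimation of a T x C matrix along time
downsample_matrix <- function(x, factor) {
  if (factor <= 1L) return(x)
  Td <- nrow(x) %/% factor
  out <- matrix(0, Td, ncol(x))
  for (c in seq_len(ncol(x))) {
    out[, c] <- colMeans(matrix(x[seq_len(Td * factor), c], nrow = factor))
  }
  out
}

#' Assemble a model-ready dataset from a cohort
#'
#' Builds one sample per subject and MVC trial: the multi-channel trial
#' window (sEMG rectified to its envelope, then block-mean decimated
#' together with the signed strain channels), the nine MVC-normalized
#' engineered features (mean of the normalized sub-window values of the
#' sEMG channels within the trial), and the three demographic covariates
#' (sex, age, grip strength). The modality switch restricts the raw
#' stream to the sEMG channels, the strain channels, or both, supporting
#' the modality-ablation comparison without any model change.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param feature_table Normalized feature table from
#'   [mvc_normalize()]; computed from the cohort when `NULL`.
#' @param modality `"both"`, `"semg"` or `"strain"`.
#' @param downsample Block-mean decimation factor for raw windows.
#' @return A `fusion_dataset`: list with `windows` (list of T x C
#'   matrices), `features` (n x 9 matrix), `demo` (n x 3 matrix), `label`
#'   (factor healthy/sarcopenia), `subject_id`, `trial`, `channels`.
#' @export
build_dataset <- function(cohort, feature_table = NULL,
                          modality = c("both", "semg", "strain"),
                          downsample = 20) {
  modality <- match.arg(modality)
  chans <- switch(modality,
    both = c("br_semg", "br_strain", "fds_semg", "fds_strain"),
    semg = c("br_semg", "fds_semg"),
    strain = c("br_strain", "fds_strain")
  )
  if (is.null(feature_table)) {
    feature_table <- mvc_normalize(extract_features(cohort))
  }
  feats <- feature_names()
  # end-of-hold sub-window values: the fatigue-sensitive reading that
  # survives MVC-mean normalization (see group_compare)
  ftab <- select_windows(feature_table, "last")
  fsum <- ftab |>
    dplyr::group_by(.data$subject_id, .data$trial) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feats), mean), .groups = "drop")

  windows <- list()
  feature_m <- list()
  demo_m <- list()
  label <- character(0)
  subject <- character(0)
  trial_id <- integer(0)
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort$recording[[i]]
    tb <- rec$trial_boundaries
    for (tr in seq_len(nrow(tb))) {
      # sEMG enters as a rectified envelope (|x|, then block-mean): the
      # signed interference pattern averages to ~0 under decimation,
      # while amplitude and its within-hold drift are what carry group
      # information; the slow strain waveform keeps its sign
      X <- sapply(chans, function(ch) {
        x <- rec$channels[[ch]][(tb[tr, 1] + 1L):tb[tr, 2]]
        if (grepl("semg$", ch)) abs(x) else x
      })
      fr <- fsum[fsum$subject_id == cohort$subject_id[i] & fsum$trial == tr, feats]
      if (nrow(fr) != 1L) {
        abort(sprintf(
          "no (or ambiguous) feature row for subject %s trial %d",
          cohort$subject_id[i], tr
        ))
      }
      windows[[length(windows) + 1L]] <- downsample_matrix(X, downsample)
      feature_m[[length(feature_m) + 1L]] <- as.numeric(fr[1, ])
      demo_m[[length(demo_m) + 1L]] <- c(
        sex = as.numeric(cohort$sex[i] == "male"),
        age = cohort$age[i],
        grip = cohort$grip_kg[i]
      )
      label <- c(label, cohort$group_label[i])
      subject <- c(subject, cohort$subject_id[i])
      trial_id <- c(trial_id, tr)
    }
  }
  structure(
    list(
      windows = windows,
      features = do.call(rbind, feature_m),
      demo = do.call(rbind, demo_m),
      label = factor(label, levels = c("healthy", "sarcopenia")),
      subject_id = subject,
      trial = trial_id,
      channels = chans
    ),
    class = "fusion_dataset"
  )
}

#' @export
print.fusion_dataset <- function(x, ...) {
  cat(sprintf(
    "<fusion_dataset: %d samples (%d subjects), windows %d x %d, channels: %s>\n",
    length(x$windows), length(unique(x$subject_id)),
    nrow(x$windows[[1]]), ncol(x$windows[[1]]),
    paste(x$channels, collapse = ", ")
  ))
  invisible(x)
}

#' Subset a fusion dataset by sample index
#'
#' @param dataset A `fusion_dataset`.
#' @param idx Integer sample indices.
#' @return The subset `fusion_dataset`.
#' @export
dataset_subset <- function(dataset, idx) {
  structure(
    list(
      windows = dataset$windows[idx],
      features = dataset$features[idx, , drop = FALSE],
      demo = dataset$demo[idx, , drop = FALSE],
      label = dataset$label[idx],
      subject_id = dataset$subject_id[idx],
      trial = dataset$trial[idx],
      channels = dataset$channels
    ),
    class = "fusion_dataset"
  )
}

# parameter initialization for the three architectures -----------------------

init_params <- function(arch, cfg, input_spec) {
  k <- cfg$conv_kernel
  p <- cfg$pool_size
  F1 <- cfg$conv_filters[1]
  F2 <- cfg$conv_filters[2]
  Tn <- input_spec$steps
  C <- input_spec$channels
  params <- list()
  dims <- list()
  if (arch %in% c("cnn_lstm", "cnn")) {
    T1 <- (Tn - k + 1L) %/% p
    T2 <- (T1 - k + 1L) %/% p
    if (T2 < 2L) abort("window too short for the convolution/pooling stack")
    params$W1 <- glorot(k * C, F1)
    params$b1 <- numeric(F1)
    params$W2 <- glorot(k * F1, F2)
    params$b2 <- numeric(F2)
    dims$T2 <- T2
  }
  zdim <- 0L
  if (arch == "cnn_lstm") {
    lp <- lstm_init(F2, cfg$lstm_hidden)
    params$Wx <- lp$Wx
    params$Wh <- lp$Wh
    params$bl <- lp$b
    zdim <- cfg$lstm_hidden
  } else if (arch == "cnn") {
    zdim <- dims$T2 * F2
  } else if (arch == "lstm") {
    lp <- lstm_init(C, cfg$lstm_hidden)
    params$Wx <- lp$Wx
    params$Wh <- lp$Wh
    params$bl <- lp$b
    zdim <- cfg$lstm_hidden
  }
  if (arch == "cnn_lstm" && cfg$use_features) {
    params$Wf <- glorot(input_spec$n_features, cfg$mapping_channels)
    params$bf <- numeric(cfg$mapping_channels)
    zdim <- zdim + cfg$mapping_channels
  }
  if (arch == "cnn_lstm" && cfg$use_demo) {
    params$Wd <- glorot(input_spec$n_demo, cfg$mapping_channels)
    params$bd <- numeric(cfg$mapping_channels)
    zdim <- zdim + cfg$mapping_channels
  }
  params$Wz <- glorot(zdim, cfg$dense_hidden)
  params$bz <- numeric(cfg$dense_hidden)
  params$Wo <- glorot(cfg$dense_hidden, 2L)
  params$bo <- numeric(2L)
  attr(params, "zdim") <- zdim
  params
}

# single-sample forward pass; returns probs, the fused representation z,
# and every intermediate needed for the backward pass
net_fwd <- function(arch, params, X, fv, dv, cfg, dropmask = NULL) {
  cache <- list()
  if (arch == "lstm") {
    Z <- downsample_matrix(X, cfg$lstm_input_pool)
    ls <- lstm_fwd(Z, list(Wx = params$Wx, Wh = params$Wh, b = params$bl),
      cfg$lstm_hidden)
    z <- ls$out
    cache$ls <- ls
    cache$Z <- Z
  } else {
    c1 <- conv1d_fwd(X, params$W1, params$b1, cfg$conv_kernel)
    A1 <- relu(c1$out)
    P1 <- maxpool_fwd(A1, cfg$pool_size)
    c2 <- conv1d_fwd(P1$out, params$W2, params$b2, cfg$conv_kernel)
    A2 <- relu(c2$out)
    P2 <- maxpool_fwd(A2, cfg$pool_size)
    cache[c("c1", "A1", "P1", "c2", "A2", "P2")] <- list(c1, A1, P1, c2, A2, P2)
    if (arch == "cnn_lstm") {
      ls <- lstm_fwd(P2$out, list(Wx = params$Wx, Wh = params$Wh, b = params$bl),
        cfg$lstm_hidden)
      zA <- ls$out
      cache$ls <- ls
      z <- zA
      if (cfg$use_features) {
        aB <- as.numeric(fv %*% params$Wf) + params$bf
        hB <- relu(aB)
        cache$aB <- aB
        z <- c(z, hB)
      }
      if (cfg$use_demo) {
        aC <- as.numeric(dv %*% params$Wd) + params$bd
        hC <- relu(aC)
        cache$aC <- aC
        z <- c(z, hC)
      }
    } else { # cnn: flatten
      z <- as.numeric(P2$out)
    }
  }
  a1 <- as.numeric(z %*% params$Wz) + params$bz
  h1 <- relu(a1)
  if (!is.null(dropmask)) h1 <- h1 * dropmask
  logits <- as.numeric(h1 %*% params$Wo) + params$bo
  cache$z <- z
  cache$a1 <- a1
  cache$h1 <- h1
  list(probs = softmax(logits), cache = cache)
}

net_bwd <- function(arch, params, fwd, y_index, X, fv, dv, cfg, dropmask = NULL) {
  cache <- fwd$cache
  dlogits <- fwd$probs
  dlogits[y_index] <- dlogits[y_index] - 1
  g <- list()
  g$Wo <- outer(cache$h1, dlogits)
  g$bo <- dlogits
  dh1 <- as.numeric(params$Wo %*% dlogits)
  if (!is.null(dropmask)) dh1 <- dh1 * dropmask
  da1 <- dh1 * (cache$a1 > 0)
  g$Wz <- outer(cache$z, da1)
  g$bz <- da1
  dz <- as.numeric(params$Wz %*% da1)

  if (arch == "lstm") {
    lb <- lstm_bwd(cache$ls, list(Wx = params$Wx, Wh = params$Wh, b = params$bl), dz)
    g$Wx <- lb$dWx
    g$Wh <- lb$dWh
    g$bl <- lb$db
    return(g)
  }

  H <- cfg$lstm_hidden
  if (arch == "cnn_lstm") {
    dzA <- dz[seq_len(H)]
    off <- H
    if (cfg$use_features) {
      dhB <- dz[(off + 1L):(off + cfg$mapping_channels)]
      daB <- dhB * (cache$aB > 0)
      g$Wf <- outer(as.numeric(fv), daB)
      g$bf <- daB
      off <- off + cfg$mapping_channels
    }
    if (cfg$use_demo) {
      dhC <- dz[(off + 1L):(off + cfg$mapping_channels)]
      daC <- dhC * (cache$aC > 0)
      g$Wd <- outer(as.numeric(dv), daC)
      g$bd <- daC
    }
    lb <- lstm_bwd(cache$ls, list(Wx = params$Wx, Wh = params$Wh, b = params$bl), dzA)
    g$Wx <- lb$dWx
    g$Wh <- lb$dWh
    g$bl <- lb$db
    dP2 <- lb$dZ
  } else { # cnn
    dP2 <- matrix(dz, nrow = nrow(cache$P2$out), ncol = ncol(cache$P2$out))
  }

  dA2 <- maxpool_bwd(cache$P2, dP2) * (cache$c2$out > 0)
  cb2 <- conv1d_bwd(cache$c2, params$W2, dA2)
  g$W2 <- cb2$dW
  g$b2 <- cb2$db
  dA1 <- maxpool_bwd(cache$P1, cb2$dX) * (cache$c1$out > 0)
  cb1 <- conv1d_bwd(cache$c1, params$W1, dA1)
  g$W1 <- cb1$dW
  g$b1 <- cb1$db
  g
}

# shared trainer for the three network architectures
train_net <- function(dataset, config, arch) {
  n <- length(dataset$windows)
  if (n < 2L || nlevels(droplevels(dataset$label)) < 2L) {
    abort("training needs at least 2 samples covering both classes")
  }
  set.seed(config$seed)

  norm <- list(
    f_center = colMeans(dataset$features),
    f_scale = pmax(apply(dataset$features, 2, sd), 1e-8),
    d_center = colMeans(dataset$demo),
    d_scale = pmax(apply(dataset$demo, 2, sd), 1e-8)
  )
  Fm <- sweep(sweep(dataset$features, 2, norm$f_center), 2, norm$f_scale, "/")
  Dm <- sweep(sweep(dataset$demo, 2, norm$d_center), 2, norm$d_scale, "/")

  input_spec <- list(
    steps = nrow(dataset$windows[[1]]),
    channels = ncol(dataset$windows[[1]]),
    channel_names = dataset$channels,
    n_features = ncol(dataset$features),
    n_demo = ncol(dataset$demo)
  )
  params <- init_params(arch, config, input_spec)
  state <- adam_init(params)
  y <- as.integer(dataset$label)
  dh <- config$dense_hidden

  history <- matrix(0, config$epochs, 2, dimnames = list(NULL, c("loss", "accuracy")))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    ep_correct <- 0L
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      grads <- NULL
      for (i in idx) {
        mask <- if (config$dropout > 0) {
          (runif(dh) >= config$dropout) / (1 - config$dropout)
        } else {
          NULL
        }
        fwd <- net_fwd(arch, params, dataset$windows[[i]], Fm[i, ], Dm[i, ],
          config, dropmask = mask)
        g <- net_bwd(arch, params, fwd, y[i], dataset$windows[[i]], Fm[i, ],
          Dm[i, ], config, dropmask = mask)
        grads <- add_grads(grads, g)
        ep_loss <- ep_loss - log(max(fwd$probs[y[i]], 1e-12))
        ep_correct <- ep_correct + as.integer(which.max(fwd$probs) == y[i])
      }
      upd <- adam_step(params, scale_grads(grads, 1 / length(idx)), state,
        config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    history[ep, ] <- c(ep_loss / n, ep_correct / n)
  }

  structure(
    list(
      arch = arch,
      params = params,
      config = config,
      norm = norm,
      input_spec = input_spec,
      classes = levels(dataset$label),
      history = tibble(
        epoch = seq_len(config$epochs),
        loss = history[, "loss"],
        accuracy = history[, "accuracy"]
      )
    ),
    class = c(if (arch == "cnn_lstm") "fusion_model", "sarc_net")
  )
}

#' Training configuration of the packaged evaluation study
#'
#' The fixed, reduced-size configuration used by the package's own
#' cross-validated evaluation study (and by `scripts/acceptance.R`): a
#' compact version of the fusion network (8/16 convolution filters,
#' 15 epochs, learning rate 2e-3) that converges reliably on the
#' synthetic screening task while keeping a 10-fold, three-modality study
#' tractable on a single CPU.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [fusion_config()].
#' @return A [fusion_config()].
#' @export
study_config <- function(seed = 1L, ...) {
  fusion_config(
    epochs = 15, conv_filters = c(8, 16), learning_rate = 2e-3,
    seed = seed, ...
  )
}

#' Train the three-stream CNN-LSTM fusion classifier
#'
#' End-to-end training of the fusion network on a [build_dataset()]
#' dataset with Adam and softmax cross-entropy. The feature and
#' demographics streams are z-scored with statistics computed from the
#' training data only (stored in the model and re-applied at prediction
#' time, so no information leaks from held-out data). The full train /
#' predict cycle is deterministic given `config$seed`.
#'
#' @param dataset A `fusion_dataset`.
#' @param config A [fusion_config()].
#' @return A `fusion_model` with the learned parameters, the config, the
#'   per-epoch `history` (loss, training accuracy) and the input spec.
#' @export
train_fusion <- function(dataset, config = fusion_config()) {
  train_net(dataset, config, "cnn_lstm")
}

#' @export
print.sarc_net <- function(x, ...) {
  cat(sprintf(
    "<%s network: %d epochs, final training accuracy %.3f, loss %.4f>\n",
    x$arch, nrow(x$history),
    x$history$accuracy[nrow(x$history)], x$history$loss[nrow(x$history)]
  ))
  invisible(x)
}

#' Class probabilities from a trained screening model
#'
#' @param object A trained model (`fusion_model`, network or classical
#'   baseline).
#' @param dataset A `fusion_dataset` of samples to score.
#' @param ... Unused.
#' @return Numeric matrix (samples x 2) with columns `healthy` and
#'   `sarcopenia`; rows sum to 1.
#' @export
predict_proba <- function(object, dataset, ...) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.sarc_net <- function(object, dataset, ...) {
  if (nrow(dataset$windows[[1]]) != object$input_spec$steps ||
    ncol(dataset$windows[[1]]) != object$input_spec$channels) {
    abort("dataset window shape does not match the model's input spec")
  }
  Fm <- sweep(sweep(dataset$features, 2, object$norm$f_center), 2,
    object$norm$f_scale, "/")
  Dm <- sweep(sweep(dataset$demo, 2, object$norm$d_center), 2,
    object$norm$d_scale, "/")
  n <- length(dataset$windows)
  out <- matrix(0, n, 2, dimnames = list(NULL, object$classes))
  for (i in seq_len(n)) {
    out[i, ] <- net_fwd(object$arch, object$params, dataset$windows[[i]],
      Fm[i, ], Dm[i, ], object$config)$probs
  }
  out
}

#' Train a comparison baseline classifier
#'
#' The classical baselines (`"svm"`, `"rf"`) consume the nine engineered
#' features plus demographics; the network baselines (`"cnn"`, `"lstm"`)
#' consume the raw windows only. All baselines share the
#' [predict_proba()] interface with the fusion model.
#'
#' @param kind One of `"svm"`, `"rf"`, `"cnn"`, `"lstm"`.
#' @param dataset A `fusion_dataset`.
#' @param seed Integer seed.
#' @param config A [fusion_config()] (used by the network baselines).
#' @return A trained baseline model.
#' @export
train_baseline <- function(kind, dataset, seed = 1L,
                           config = fusion_config(seed = seed)) {
  if (!kind %in% c("svm", "rf", "cnn", "lstm")) {
    abort(sprintf("unknown baseline kind \"%s\"", kind))
  }
  if (kind %in% c("cnn", "lstm")) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    return(train_net(dataset, cfg, kind))
  }
  X <- cbind(dataset$features, dataset$demo)
  colnames(X) <- c(
    paste0("f", seq_len(ncol(dataset$features))),
    c("sex", "age", "grip")
  )
  y <- droplevels(dataset$label)
  if (nlevels(y) < 2L) abort("training needs both classes")
  set.seed(seed)
  if (kind == "svm") {
    fit <- e1071::svm(X, y, probability = TRUE, kernel = "radial")
    structure(list(fit = fit, classes = levels(y)), class = "svm_baseline")
  } else {
    fit <- randomForest::randomForest(X, y)
    structure(list(fit = fit, classes = levels(y)), class = "rf_baseline")
  }
}

baseline_design <- function(dataset) {
  X <- cbind(dataset$features, dataset$demo)
  colnames(X) <- c(
    paste0("f", seq_len(ncol(dataset$features))),
    c("sex", "age", "grip")
  )
  X
}

#' @export
predict_proba.svm_baseline <- function(object, dataset, ...) {
  pr <- attr(
    predict(object$fit, baseline_design(dataset), probability = TRUE),
    "probabilities"
  )
  pr[, c("healthy", "sarcopenia"), drop = FALSE]
}

#' @export
predict_proba.rf_baseline <- function(object, dataset, ...) {
  pr <- predict(object$fit, baseline_design(dataset), type = "prob")
  pr[, c("healthy", "sarcopenia"), drop = FALSE]
}
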