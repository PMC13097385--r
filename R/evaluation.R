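#' Subject-level stratified k-fold cross-validation
#'
#' Splits *subjects* (never individual windows) into k label-stratified
#' folds, trains the requested model on the training-fold samples and
#' scores the held-out samples, so that no window of a test subject is
#' ever seen during training. Feature/demographic standardization happens
#' inside training on the training fold only.
#'
#' @param dataset A `fusion_dataset` from [build_dataset()].
#' @param model_spec `"cnn_lstm"` (the fusion model) or a baseline kind
#'   (`"svm"`, `"rf"`, `"cnn"`, `"lstm"`).
#' @param k Number of folds (at most the number of subjects).
#' @param seed Integer seed (fold assignment and per-fold training).
#' @param config A [fusion_config()] used by the network models.
#' @return A `cv_report`: fold assignments, per-fold accuracy, pooled
#'   2 x 2 confusion matrix (rows = truth, columns = prediction), pooled
#'   ROC points and AUC, mean accuracy, and the per-sample scores.
#' @export
kfold_cv <- function(dataset, model_spec = "cnn_lstm", k = 10, seed = 1L,
                     config = fusion_config(seed = seed)) {
  subjects <- unique(dataset$subject_id)
  if (k > length(subjects)) abort("`k` cannot exceed the number of subjects")
  subj_label <- dataset$label[match(subjects, dataset$subject_id)]

  set.seed(seed)
  fold_of <- setNames(integer(length(subjects)), subjects)
  offset <- 0L
  for (lv in levels(subj_label)) {
    s <- sample(subjects[subj_label == lv])
    # continue the fold cycle across label groups so all k folds are filled
    fold_of[s] <- ((offset + seq_along(s) - 1L) %% k) + 1L
    offset <- offset + length(s)
  }

  scores <- numeric(length(dataset$label))
  predicted <- character(length(dataset$label))
  fold_rows <- vector("list", k)
  for (fold in seq_len(k)) {
    test_subj <- names(fold_of)[fold_of == fold]
    test_idx <- which(dataset$subject_id %in% test_subj)
    train_idx <- setdiff(seq_along(dataset$subject_id), test_idx)
    train_ds <- dataset_subset(dataset, train_idx)
    model <- if (model_spec == "cnn_lstm") {
      cfg <- config
      cfg$seed <- derive_seed(seed, fold)
      train_fusion(train_ds, cfg)
    } else {
      train_baseline(model_spec, train_ds,
        seed = derive_seed(seed, fold), config = config
      )
    }
    pr <- predict_proba(model, dataset_subset(dataset, test_idx))
    scores[test_idx] <- pr[, "sarcopenia"]
    predicted[test_idx] <- colnames(pr)[max.col(pr, ties.method = "first")]
    fold_rows[[fold]] <- tibble(
      fold = fold,
      n = length(test_idx),
      accuracy = mean(predicted[test_idx] == as.character(dataset$label[test_idx]))
    )
  }

  truth <- factor(dataset$label, levels = c("healthy", "sarcopenia"))
  pred <- factor(predicted, levels = c("healthy", "sarcopenia"))
  confusion <- table(truth = truth, prediction = pred)
  roc <- roc_auc(scores, truth == "sarcopenia")

  # subject-level screening decision: trials vote via their mean score
  subj_score <- tapply(scores, dataset$subject_id, mean)
  subj_truth <- tapply(as.character(truth), dataset$subject_id, `[`, 1)
  subject_accuracy <- mean(
    ifelse(subj_score > 0.5, "sarcopenia", "healthy") == subj_truth
  )

  structure(
    list(
      model_spec = model_spec,
      k = k,
      fold_assignments = tibble(
        subject_id = names(fold_of),
        fold = unname(fold_of)
      ),
      per_fold = list_rbind(fold_rows),
      mean_accuracy = mean(pred == truth),
      subject_accuracy = subject_accuracy,
      confusion_matrix = unclass(confusion),
      roc_points = roc$roc_points,
      auc = roc$auc,
      scores = tibble(
        subject_id = dataset$subject_id, trial = dataset$trial,
        truth = as.character(truth), predicted = predicted, score = scores
      )
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report %s: %d-fold, mean accuracy %.3f, AUC %.3f>\n",
    x$model_spec, x$k, x$mean_accuracy, x$auc
  ))
  print(x$confusion_matrix)
  invisible(x)
}

#' Empirical ROC curve and area under it
#'
#' Sweeps every distinct score as a threshold, computes (FPR, TPR), and
#' integrates by the trapezoidal rule. With tied scores handled by
#' grouping, the trapezoidal area equals the normalized Mann-Whitney
#' U statistic `U / (n_pos * n_neg)`.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical (or coercible) vector marking the positive class.
#' @return List with `roc_points` (tibble `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("`scores`/`labels` length mismatch")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present; AUC undefined")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores so each distinct threshold yields one ROC point
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- tibble(
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos),
    threshold = c(Inf, s[last])
  )
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(roc_points = pts, auc = auc)
}

#' t-SNE embedding of a learned feature space
#'
#' Deterministic (seeded) two-dimensional t-distributed stochastic
#' neighbour embedding, used to visualize how well the network's fused
#' representation separates the screening groups.
#'
#' @param feature_matrix Numeric matrix (samples x dimensions).
#' @param perplexity t-SNE perplexity; at least `3 * perplexity` samples
#'   are required.
#' @param seed Integer seed.
#' @return Tibble with columns `ts1`, `ts2` (one row per sample).
#' @export
tsne_embed <- function(feature_matrix, perplexity = 30, seed = 1L) {
  feature_matrix <- as.matrix(feature_matrix)
  if (nrow(feature_matrix) < 3 * perplexity) {
    abort("t-SNE needs at least 3 * perplexity samples")
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(feature_matrix,
    dims = 2, perplexity = perplexity, theta = 0, # exact at these sizes
    check_duplicates = FALSE, pca = FALSE, verbose = FALSE
  )
  tibble(ts1 = fit$Y[, 1], ts2 = fit$Y[, 2])
}

#' Fused-layer activations of a trained network
#'
#' Returns the post-concatenation dense-layer activations (the "learned
#' features" that feed the softmax classifier), the usual input to
#' [tsne_embed()].
#'
#' @param model A trained `sarc_net` (e.g. a `fusion_model`).
#' @param dataset A `fusion_dataset`.
#' @return Numeric matrix (samples x `dense_hidden`).
#' @export
fusion_activations <- function(model, dataset) {
  Fm <- sweep(sweep(dataset$features, 2, model$norm$f_center), 2,
    model$norm$f_scale, "/")
  Dm <- sweep(sweep(dataset$demo, 2, model$norm$d_center), 2,
    model$norm$d_scale, "/")
  n <- length(dataset$windows)
  out <- matrix(0, n, model$config$dense_hidden)
  for (i in seq_len(n)) {
    fwd <- net_fwd(model$arch, model$params, dataset$windows[[i]],
      Fm[i, ], Dm[i, ], model$config)
    out[i, ] <- fwd$cache$h1
  }
  out
}
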