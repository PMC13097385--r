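#' Tidy a cross-validation report
#'
#' @param x A `cv_report` from [kfold_cv()].
#' @param ... Unused.
#' @return One row per fold with `fold`, `n`, `accuracy`.
#' @export
tidy.cv_report <- function(x, ...) x$per_fold

#' @rdname tidy.cv_report
#' @return For `glance()`: a one-row summary with the model spec, k,
#'   mean accuracy and AUC.
#' @export
glance.cv_report <- function(x, ...) {
  tibble(
    model_spec = x$model_spec,
    k = x$k,
    n_subjects = nrow(x$fold_assignments),
    n_samples = sum(x$confusion_matrix),
    mean_accuracy = x$mean_accuracy,
    subject_accuracy = x$subject_accuracy,
    auc = x$auc
  )
}

#' Tidy a trained network's training history
#'
#' @param x A `sarc_net` (e.g. `fusion_model`).
#' @param ... Unused.
#' @return One row per epoch with `epoch`, `loss`, `accuracy`.
#' @export
tidy.sarc_net <- function(x, ...) x$history

#' @rdname tidy.sarc_net
#' @export
glance.sarc_net <- function(x, ...) {
  tibble(
    arch = x$arch,
    epochs = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    final_accuracy = x$history$accuracy[nrow(x$history)],
    peak_accuracy = max(x$history$accuracy)
  )
}

#' Tidy a Shapley attribution set
#'
#' @param x An `attribution_set`.
#' @param ... Unused.
#' @return Long tibble with `sample`, `feature`, `shap`, `feature_value`
#'   and the Monte-Carlo `se`.
#' @export
tidy.attribution_set <- function(x, ...) {
  n <- nrow(x$shap)
  p <- ncol(x$shap)
  tibble(
    sample = rep(seq_len(n), times = p),
    feature = rep(x$feature_names, each = n),
    shap = as.numeric(x$shap),
    feature_value = as.numeric(x$values),
    se = as.numeric(x$se)
  )
}

#' @rdname tidy.attribution_set
#' @export
glance.attribution_set <- function(x, ...) {
  tibble(
    n_samples = nrow(x$shap),
    n_features = ncol(x$shap),
    baseline_value = x$baseline_value,
    max_local_accuracy_gap = max(abs(
      rowSums(x$shap) + (x$baselines %||% x$baseline_value) - x$predictions
    ))
  )
}
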