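#' Permutation-sampling Shapley attributions
#'
#' Model-agnostic Shapley-value estimator: for each explained sample and
#' each of `n_permutations` random feature orderings, features are
#' switched one by one from a randomly drawn background row to the
#' sample's own values, and each feature is credited with the change in
#' model output it causes. Averaging over orderings gives an unbiased
#' estimate of the exact Shapley value with "absent" features imputed
#' from the background distribution. Within each ordering the credited
#' changes telescope, so attributions satisfy local accuracy up to
#' Monte-Carlo error: per sample, `sum(shap) + baseline` matches the
#' model output.
#'
#' @param model_fn Function mapping a numeric matrix (rows = feature
#'   vectors) to a numeric vector of scalar scores.
#' @param samples Matrix or data frame of samples to explain (rows).
#' @param background Matrix or data frame of background rows used to
#'   impute absent features.
#' @param n_permutations Random orderings per sample (>= 1).
#' @param seed Integer seed.
#' @return An `attribution_set`: list with `shap` (samples x features),
#'   `se` (Monte-Carlo standard errors, same shape), `baseline_value`
#'   (mean model output over the background draws), `baselines` (the
#'   per-sample background means, against which local accuracy holds),
#'   `feature_names`, `values` (the explained samples) and `predictions`
#'   (model outputs for the explained samples).
#' @export
shapley_attributions <- function(model_fn, samples, background,
                                 n_permutations = 200, seed = 1L) {
  samples <- as.matrix(samples)
  background <- as.matrix(background)
  if (!nrow(background)) abort("`background` must be non-empty")
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  p <- ncol(samples)
  feats <- colnames(samples) %||% paste0("x", seq_len(p))

  set.seed(seed)
  n <- nrow(samples)
  shap <- matrix(0, n, p, dimnames = list(NULL, feats))
  se <- matrix(0, n, p, dimnames = list(NULL, feats))
  baselines <- numeric(n)

  for (i in seq_len(n)) {
    x <- samples[i, ]
    orders <- replicate(n_permutations, sample.int(p), simplify = FALSE)
    bg_idx <- sample.int(nrow(background), n_permutations, replace = TRUE)
    # all coalition states of all orderings, evaluated in one model call:
    # per ordering, p + 1 rows running from the background row to x
    states <- matrix(0, n_permutations * (p + 1L), p)
    row <- 0L
    for (r in seq_len(n_permutations)) {
      z <- background[bg_idx[r], ]
      states[row + 1L, ] <- z
      for (j in seq_len(p)) {
        z[orders[[r]][j]] <- x[orders[[r]][j]]
        states[row + 1L + j, ] <- z
      }
      row <- row + p + 1L
    }
    colnames(states) <- feats
    f <- model_fn(states)
    contrib <- matrix(0, n_permutations, p)
    row <- 0L
    for (r in seq_len(n_permutations)) {
      d <- diff(f[(row + 1L):(row + p + 1L)])
      contrib[r, orders[[r]]] <- d
      row <- row + p + 1L
    }
    shap[i, ] <- colMeans(contrib)
    se[i, ] <- apply(contrib, 2, sd) / sqrt(n_permutations)
    baselines[i] <- mean(f[seq(1L, by = p + 1L, length.out = n_permutations)])
  }

  structure(
    list(
      shap = shap,
      se = se,
      baseline_value = mean(baselines),
      baselines = baselines,
      feature_names = feats,
      values = samples,
      predictions = as.numeric(model_fn(samples))
    ),
    class = "attribution_set"
  )
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf(
    "<attribution_set: %d samples x %d features, baseline %.4f>\n",
    nrow(x$shap), ncol(x$shap), x$baseline_value
  ))
  print(utils::head(summary_ranking(x), 5))
  invisible(x)
}

#' Rank features by mean absolute attribution
#'
#' @param attribution_set An `attribution_set` from
#'   [shapley_attributions()].
#' @return Tibble with `feature` and `mean_abs_shap`, sorted descending
#'   (alphabetical on ties), plus a `rank` column.
#' @export
summary_ranking <- function(attribution_set) {
  if (!nrow(attribution_set$shap)) abort("empty attribution set")
  out <- tibble(
    feature = attribution_set$feature_names,
    mean_abs_shap = colMeans(abs(attribution_set$shap))
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap), .data$feature)
  out$rank <- seq_len(nrow(out))
  out
}

#' Shapley attributions of the fusion model over its tabular streams
#'
#' Explains the fusion network's sarcopenia probability with respect to
#' the nine engineered features plus the three demographic covariates,
#' holding each explained sample's raw signal window fixed (the raw
#' stream is not attributed sample-by-sample). Background imputation
#' draws tabular values from the given background samples.
#'
#' @param model A trained `fusion_model`.
#' @param dataset A `fusion_dataset`.
#' @param idx Indices of the samples to explain.
#' @param background_idx Indices of the background samples (default: up
#'   to 50 drawn with the seed).
#' @param n_permutations,seed Passed to [shapley_attributions()].
#' @return An `attribution_set` over the 12 tabular inputs.
#' @export
shapley_fusion <- function(model, dataset, idx,
                           background_idx = NULL,
                           n_permutations = 100, seed = 1L) {
  set.seed(seed)
  if (is.null(background_idx)) {
    background_idx <- sample(seq_along(dataset$windows),
      min(50L, length(dataset$windows))
    )
  }
  tab <- cbind(dataset$features, dataset$demo)
  colnames(tab) <- c(feature_names(), "sex", "age", "grip")
  background <- tab[background_idx, , drop = FALSE]

  sets <- lapply(seq_along(idx), function(ii) {
    i <- idx[ii]
    win <- dataset$windows[[i]]
    model_fn <- function(X) {
      Fm <- sweep(sweep(X[, seq_len(9L), drop = FALSE], 2, model$norm$f_center),
        2, model$norm$f_scale, "/")
      Dm <- sweep(sweep(X[, 10:12, drop = FALSE], 2, model$norm$d_center),
        2, model$norm$d_scale, "/")
      vapply(seq_len(nrow(X)), function(r) {
        net_fwd(model$arch, model$params, win, Fm[r, ], Dm[r, ],
          model$config)$probs[2]
      }, numeric(1))
    }
    shapley_attributions(model_fn, tab[i, , drop = FALSE], background,
      n_permutations = n_permutations, seed = derive_seed(seed, ii)
    )
  })

  structure(
    list(
      shap = do.call(rbind, lapply(sets, `[[`, "shap")),
      se = do.call(rbind, lapply(sets, `[[`, "se")),
      baseline_value = mean(sapply(sets, `[[`, "baseline_value")),
      # each sample keeps its own baseline: the fixed raw window differs
      # between samples, so local accuracy is a per-sample identity
      baselines = unlist(lapply(sets, `[[`, "baselines")),
      feature_names = colnames(tab),
      values = tab[idx, , drop = FALSE],
      predictions = unlist(lapply(sets, `[[`, "predictions"))
    ),
    class = "attribution_set"
  )
}
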