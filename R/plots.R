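#' Violin plot of engineered features by screening group
#'
#' The standard group-comparison figure for the engineering stage:
#' distributions of selected MVC-normalized features in the healthy and
#' sarcopenia groups, one subject-level mean per point.
#'
#' @param feature_table (Normalized) feature table with a `group_label`
#'   column.
#' @param features Feature names to show.
#' @param window Window selection (see [group_compare()]).
#' @return A ggplot object.
#' @export
plot_feature_violin <- function(feature_table,
                                features = c("rms", "mav", "iemg", "wl"),
                                window = "last") {
  tab <- select_windows(feature_table, window)
  long <- tab |>
    dplyr::group_by(.data$subject_id, .data$group_label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(features), mean), .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(features),
      names_to = "feature", values_to = "value"
    )
  ggplot(long, aes(x = .data$group_label, y = .data$value, fill = .data$group_label)) +
    geom_violin(alpha = 0.6, trim = FALSE) +
    geom_jitter(width = 0.08, size = 0.8, alpha = 0.6) +
    facet_wrap(~ .data$feature, scales = "free_y") +
    labs(x = NULL, y = "MVC-normalized value", fill = NULL) +
    theme_minimal()
}

#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot(object$roc_points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "steelblue") +
    geom_step(colour = "firebrick", linewidth = 0.8) +
    coord_equal() +
    labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (%s), AUC = %.3f", object$model_spec, object$auc)
    ) +
    theme_minimal()
}

#' Confusion-matrix heatmap of a cross-validation report
#'
#' @param report A `cv_report`.
#' @param normalize `"row"` (per-truth-class probabilities), `"all"`
#'   (global proportions) or `"none"` (counts).
#' @return A ggplot object.
#' @export
plot_confusion <- function(report, normalize = c("row", "all", "none")) {
  normalize <- match.arg(normalize)
  cm <- report$confusion_matrix
  vals <- switch(normalize,
    row = sweep(cm, 1, pmax(rowSums(cm), 1), "/"),
    all = cm / sum(cm),
    none = cm
  )
  df <- as.data.frame(as.table(vals))
  names(df) <- c("truth", "prediction", "value")
  ggplot(df, aes(x = .data$prediction, y = .data$truth, fill = .data$value)) +
    geom_tile() +
    geom_text(aes(label = ifelse(normalize == "none",
      sprintf("%d", as.integer(.data$value)), sprintf("%.2f", .data$value)
    ))) +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = "Predicted", y = "True", fill = NULL) +
    theme_minimal()
}

#' @export
autoplot.attribution_set <- function(object, ...) {
  long <- tidy.attribution_set(object)
  ranking <- summary_ranking(object)
  long$feature <- factor(long$feature, levels = rev(ranking$feature))
  long <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(value_scaled = if (diff(range(.data$feature_value)) > 0) {
      (.data$feature_value - min(.data$feature_value)) /
        diff(range(.data$feature_value))
    } else {
      0.5
    }) |>
    dplyr::ungroup()
  ggplot(long, aes(x = .data$shap, y = .data$feature, colour = .data$value_scaled)) +
    geom_jitter(height = 0.15, size = 1, alpha = 0.8) +
    scale_colour_gradient(low = "steelblue", high = "firebrick") +
    labs(
      x = "Shapley value (effect on sarcopenia probability)", y = NULL,
      colour = "Feature value\n(scaled)"
    ) +
    theme_minimal()
}

#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- expand.grid(
    time_s = object$time_bins,
    frequency_hz = object$frequency_bins
  )
  df$magnitude <- as.numeric(object$magnitude)
  ggplot(df, aes(x = .data$time_s, y = .data$frequency_hz, fill = .data$magnitude)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "Time (s)", y = "Frequency (Hz)", fill = "|STFT|") +
    theme_minimal()
}

#' Scatter plot of a t-SNE embedding coloured by group
#'
#' @param embedding Tibble from [tsne_embed()].
#' @param labels Group label per sample.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, labels) {
  df <- dplyr::mutate(embedding, label = labels)
  ggplot(df, aes(x = .data$ts1, y = .data$ts2, colour = .data$label)) +
    geom_point(size = 1.6, alpha = 0.8) +
    labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL) +
    theme_minimal()
}
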