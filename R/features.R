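#' Names of the nine engineered features
#'
#' Six Hudgins time-domain features (`rms`, `mav`, `iemg`, `wl`, `zc`,
#' `ssc`) followed by three wavelet time-frequency features (`cwt_power`,
#' `cwt_kurtosis`, `we`).
#'
#' @return Character vector of length 9.
#' @export
feature_names <- function() {
  c("rms", "mav", "iemg", "wl", "zc", "ssc", "cwt_power", "cwt_kurtosis", "we")
}

#' Hudgins time-domain features of a signal window
#'
#' Computes the six classical time-domain descriptors of sEMG activity on
#' a window of N samples x_i:
#'
#' * `rms`: `sqrt(mean(x^2))` — effective discharge amplitude;
#' * `mav`: `mean(|x|)` — mean rectified amplitude;
#' * `iemg`: `sum(|x|) * dt` — rectangle-rule discretization of the
#'   rectified-signal integral (signal-units x s);
#' * `wl`: `sum(|x[i+1] - x[i]|)` — waveform length (complexity);
#' * `zc`: sign changes whose amplitude step exceeds `epsilon`;
#' * `ssc`: slope-sign reversals whose two adjacent differences both
#'   exceed `epsilon`.
#'
#' @param window Numeric vector of at least 2 samples.
#' @param sampling_rate Sampling rate in Hz (sets `dt` for `iemg`).
#' @param epsilon Dead-band for `zc`/`ssc`; `NULL` uses the Hudgins
#'   convention of 1% of the window RMS.
#' @return One-row tibble with columns `rms`, `mav`, `iemg`, `wl`, `zc`,
#'   `ssc`.
#' @examples
#' hudgins_features(c(3, -4), sampling_rate = 1000, epsilon = 0)
#' @export
hudgins_features <- function(window, sampling_rate, epsilon = NULL) {
  n <- length(window)
  if (n < 2L) abort("`window` must have at least 2 samples")
  if (is.null(epsilon)) epsilon <- 0.01 * rms(window)
  if (epsilon < 0) abort("`epsilon` must be non-negative")

  d <- diff(window)
  zc <- sum(window[-n] * window[-1] < 0 & abs(d) > epsilon)
  d1 <- d[-(n - 1L)] # x[i] - x[i-1] for interior i
  d2 <- -d[-1L] # x[i] - x[i+1]
  ssc <- sum(d1 * d2 > 0 & abs(d1) > epsilon & abs(d2) > epsilon)

  tibble(
    rms = rms(window),
    mav = mean(abs(window)),
    iemg = sum(abs(window)) / sampling_rate,
    wl = sum(abs(d)),
    zc = as.integer(zc),
    ssc = as.integer(ssc)
  )
}

#' Wavelet time-frequency features of a signal window
#'
#' From the Morlet CWT coefficient matrix (scales x time):
#'
#' * `cwt_power`: mean squared coefficient magnitude over all scales and
#'   times (absolute power);
#' * `cwt_kurtosis`: excess kurtosis of the pooled coefficient-magnitude
#'   distribution;
#' * `we`: wavelet entropy (nats) of the scale-wise energy distribution
#'   (see [wavelet_entropy()]); low for narrowband signals concentrated on
#'   one scale, up to `log(n_scales)` for spectrally flat signals.
#'
#' @inheritParams morlet_cwt
#' @param window Numeric vector of at least 64 samples.
#' @return One-row tibble with columns `cwt_power`, `cwt_kurtosis`, `we`.
#' @export
cwt_features <- function(window, sampling_rate, n_scales = 32,
                         freq_range = c(10, 450), omega0 = 6) {
  cw <- morlet_cwt(window, sampling_rate,
    n_scales = n_scales,
    freq_range = freq_range, omega0 = omega0
  )
  mag <- Mod(cw$coefficients)
  power <- mean(mag^2)
  scale_energy <- rowSums(mag^2)
  tibble(
    cwt_power = power,
    cwt_kurtosis = e1071::kurtosis(as.numeric(mag)),
    we = if (sum(scale_energy) > 0) wavelet_entropy(scale_energy) else NA_real_
  )
}

#' Extract the nine-feature table from a cohort
#'
#' For each subject, channel and MVC trial this segments the active
#' contraction window ([segment_active_windows()]) and computes the nine
#' engineered features both at trial level (the whole active window; used
#' as the MVC normalization reference) and, optionally, on consecutive
#' non-overlapping sub-windows inside the active window. Sub-window rows
#' are what carry within-trial structure, e.g. the amplitude rise of a
#' fatiguing contraction.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (or any tibble
#'   with `subject_id`, a `recording` list-column and, optionally,
#'   `group_label`).
#' @param channels Channels to featurize.
#' @param subwindow_s Sub-window length in seconds; `NULL` disables
#'   sub-window rows.
#' @param epsilon Dead-band passed to [hudgins_features()] (`NULL` =
#'   1% of window RMS).
#' @return Tibble with identifier columns (`subject_id`, `channel`,
#'   `trial`, `window_id`, `kind` = `"trial"`/`"subwindow"`, `t1`, `t2`,
#'   `group_label` if available), the nine feature columns, and
#'   `normalized = FALSE`.
#' @export
extract_features <- function(cohort, channels = c("br_semg", "fds_semg"),
                             subwindow_s = 1, epsilon = NULL) {
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort$recording[[i]]
    fs <- rec$sampling_rate
    for (ch in channels) {
      wins <- segment_active_windows(rec, ch)
      for (w in seq_len(nrow(wins))) {
        win <- wins[w, ]
        x <- window_samples(rec, win)
        base <- dplyr::bind_cols(
          hudgins_features(x, fs, epsilon = epsilon),
          cwt_features(x, fs)
        )
        rows[[length(rows) + 1L]] <- tibble(
          subject_id = cohort$subject_id[i], channel = ch, trial = win$trial,
          window_id = sprintf("%s_%s_T%d", cohort$subject_id[i], ch, win$trial),
          kind = "trial", t1 = win$t1, t2 = win$t2,
          group_label = cohort$group_label[i] %||% NA_character_
        ) |> dplyr::bind_cols(base)

        if (!is.null(subwindow_s)) {
          L <- as.integer(round(subwindow_s * fs))
          n_sub <- length(x) %/% L
          for (s in seq_len(n_sub)) {
            xs <- x[((s - 1L) * L + 1L):(s * L)]
            sub <- dplyr::bind_cols(
              hudgins_features(xs, fs, epsilon = epsilon),
              cwt_features(xs, fs)
            )
            rows[[length(rows) + 1L]] <- tibble(
              subject_id = cohort$subject_id[i], channel = ch, trial = win$trial,
              window_id = sprintf(
                "%s_%s_T%dW%d", cohort$subject_id[i], ch, win$trial, s
              ),
              kind = "subwindow",
              t1 = win$t1 + (s - 1L) * subwindow_s,
              t2 = win$t1 + s * subwindow_s,
              group_label = cohort$group_label[i] %||% NA_character_
            ) |> dplyr::bind_cols(sub)
          }
        }
      }
    }
  }
  out <- list_rbind(rows)
  out$normalized <- FALSE
  out
}

#' Normalize features to the mean of the three MVC trials
#'
#' Every feature value is divided by the mean of the same subject's,
#' channel's and feature's three trial-level values, removing
#' inter-individual scale differences. By construction the per-subject
#' mean of the normalized *trial-level* values is exactly 1; sub-window
#' rows (if present) are divided by the same trial-mean denominators and
#' retain within-trial structure.
#'
#' @param feature_table Tibble from [extract_features()]; if no `kind`
#'   column is present all rows are treated as trial-level, and each
#'   (subject, channel) must then contribute exactly 3 rows.
#' @return The table with feature columns rescaled and
#'   `normalized = TRUE`.
#' @export
mvc_normalize <- function(feature_table) {
  feats <- intersect(feature_names(), names(feature_table))
  if (!length(feats)) abort("no feature columns found")
  if (!all(c("subject_id", "channel") %in% names(feature_table))) {
    abort("`feature_table` needs `subject_id` and `channel` columns")
  }
  tab <- feature_table
  if (!"kind" %in% names(tab)) tab$kind <- "trial"

  ref <- tab |>
    dplyr::filter(.data$kind == "trial") |>
    dplyr::count(.data$subject_id, .data$channel)
  if (any(ref$n != 3L)) {
    abort("each (subject, channel) must have exactly 3 trial-level windows")
  }

  denom <- tab |>
    dplyr::filter(.data$kind == "trial") |>
    dplyr::group_by(.data$subject_id, .data$channel) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feats), mean), .groups = "drop")
  for (f in feats) {
    zero <- denom$subject_id[denom[[f]] == 0]
    if (length(zero)) {
      abort(sprintf(
        "zero MVC trial mean for feature \"%s\" in subject(s): %s",
        f, paste(unique(zero), collapse = ", ")
      ))
    }
  }

  key <- paste(tab$subject_id, tab$channel)
  dkey <- paste(denom$subject_id, denom$channel)
  idx <- match(key, dkey)
  for (f in feats) tab[[f]] <- tab[[f]] / denom[[f]][idx]
  tab$normalized <- TRUE
  if (!"kind" %in% names(feature_table)) tab$kind <- NULL
  tab
}

# pick analysis windows out of a feature table: the last hold sub-window
# per trial, all sub-windows, or the trial-level rows; tables without
# sub-window rows fall back to whatever rows they have
select_windows <- function(feature_table, window = c("last", "all", "trial")) {
  window <- match.arg(window)
  tab <- feature_table
  if (!"kind" %in% names(tab)) {
    return(tab)
  }
  has_sub <- any(tab$kind == "subwindow")
  if (window == "trial" || !has_sub) {
    return(tab[tab$kind == "trial", ])
  }
  tab <- tab[tab$kind == "subwindow", ]
  if (window == "last") {
    tab <- tab |>
      dplyr::group_by(.data$subject_id, .data$channel, .data$trial) |>
      dplyr::slice_max(.data$t1, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  tab
}

#' Compare feature distributions between screening groups
#'
#' Aggregates the (normalized) feature table to one value per subject and
#' feature (the mean over channels, trials and sub-windows), then tests
#' each of the nine features for a group difference with a two-sided
#' Mann-Whitney U test, applying Benjamini-Hochberg correction across the
#' nine features.
#'
#' @param feature_table Tibble with feature columns, `subject_id` and a
#'   group column.
#' @param group_col Name of the group column (default `"group_label"`).
#' @param window Which windows to aggregate per subject when sub-window
#'   rows are present: `"last"` (default) uses the final hold sub-window
#'   of each trial — the end-of-contraction segment where fatigue-driven
#'   compensatory activation is maximal, and the only place a
#'   within-trial amplitude drift survives MVC-mean normalization —
#'   `"all"` uses every sub-window, `"trial"` uses the trial-level rows.
#' @return Tibble with one row per feature: group means, the U statistic,
#'   raw and BH-adjusted p-values, and `direction` (which group has the
#'   higher mean).
#' @export
group_compare <- function(feature_table, group_col = "group_label",
                          window = c("last", "all", "trial")) {
  window <- match.arg(window)
  feats <- intersect(feature_names(), names(feature_table))
  if (!group_col %in% names(feature_table)) {
    abort(sprintf("`feature_table` has no \"%s\" column", group_col))
  }
  tab <- select_windows(feature_table, window)
  groups <- unique(na.omit(tab[[group_col]]))
  if (length(groups) != 2L) abort("exactly two groups are required")

  by_subject <- tab |>
    dplyr::group_by(.data$subject_id, group = .data[[group_col]]) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feats), mean), .groups = "drop")
  if (any(table(by_subject$group) < 2L)) {
    abort("each group needs at least 2 subjects")
  }

  g1 <- groups[1]
  g2 <- groups[2]
  res <- lapply(feats, function(f) {
    x1 <- by_subject[[f]][by_subject$group == g1]
    x2 <- by_subject[[f]][by_subject$group == g2]
    wt <- suppressWarnings(wilcox.test(x1, x2, exact = FALSE))
    tibble(
      feature = f,
      mean_1 = mean(x1), mean_2 = mean(x2),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      direction = ifelse(mean(x1) > mean(x2), g1, g2)
    )
  }) |> list_rbind()
  names(res)[names(res) == "mean_1"] <- paste0("mean_", g1)
  names(res)[names(res) == "mean_2"] <- paste0("mean_", g2)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res
}
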