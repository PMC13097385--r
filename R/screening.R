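#' AWGS-2019 sarcopenia screening rules
#'
#' Applies the 2019 Asian Working Group for Sarcopenia (AWGS) case-finding
#' cut-offs to per-subject clinical measurements and returns the three
#' criterion flags together with the final classification. The cut-offs are
#' sex-specific and use strict inequalities for strength and mass:
#'
#' * low muscle strength: handgrip strength below 28 kg (men) or below
#'   18 kg (women);
#' * low muscle mass: skeletal muscle index (SMI) below 7.0 kg/m^2 (men) or
#'   below 5.7 kg/m^2 (women);
#' * poor physical performance: five-times chair-stand time of 12 s or more.
#'
#' A subject is classified `"sarcopenia"` when low muscle mass is present
#' together with low strength, poor performance, or both; `"healthy"` when
#' all three flags are absent; and `"indeterminate"` otherwise (e.g. low
#' strength with preserved mass). Missing measurements yield an explicit
#' `"missing"` classification rather than a silent default.
#'
#' @param data Data frame with one row per subject and columns `sex`
#'   (`"male"`/`"female"`), `grip_kg` (handgrip strength, kg), `smi`
#'   (skeletal muscle index, kg/m^2) and `chair_stand_s` (five-times
#'   chair-stand time, s).
#' @return The input as a tibble with logical columns `low_strength`,
#'   `low_mass`, `poor_performance` and a character `classification` column
#'   (`"healthy"`, `"sarcopenia"`, `"indeterminate"` or `"missing"`).
#' @examples
#' classify_awgs(tibble::tibble(
#'   sex = c("male", "female"),
#'   grip_kg = c(27, 25),
#'   smi = c(6.9, 6.2),
#'   chair_stand_s = c(10, 9)
#' ))
#' @export
classify_awgs <- function(data) {
  needed <- c("sex", "grip_kg", "smi", "chair_stand_s")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(data$sex %in% c("male", "female", NA))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  bad <- !is.na(data$grip_kg) & data$grip_kg <= 0 |
    !is.na(data$smi) & data$smi <= 0 |
    !is.na(data$chair_stand_s) & data$chair_stand_s <= 0
  if (any(bad)) abort("measurements must be positive where present")

  grip_cut <- ifelse(data$sex == "male", 28, 18)
  smi_cut <- ifelse(data$sex == "male", 7.0, 5.7)

  out <- as_tibble(data)
  out$low_strength <- data$grip_kg < grip_cut
  out$low_mass <- data$smi < smi_cut
  out$poor_performance <- data$chair_stand_s >= 12
  out$classification <- awgs_classification(
    out$low_strength, out$low_mass, out$poor_performance
  )
  out
}

# truth table: sarcopenia iff low_mass & (low_strength | poor_performance);
# healthy iff all flags FALSE; anything else indeterminate
awgs_classification <- function(low_strength, low_mass, poor_performance) {
  cls <- rep("indeterminate", length(low_mass))
  cls[low_mass & (low_strength | poor_performance)] <- "sarcopenia"
  cls[!low_mass & !low_strength & !poor_performance] <- "healthy"
  cls[is.na(low_strength) | is.na(low_mass) | is.na(poor_performance)] <- "missing"
  cls
}

#' Compare screening results across two visits
#'
#' Labels the health-state transition between a baseline visit and a
#' follow-up visit for the same subjects, and flags subjects where a model
#' prediction at baseline anticipated the rule-based diagnosis made only at
#' follow-up ("early-detection candidates"). This supports longitudinal
#' monitoring use, where a classifier trained on sEMG/strain recordings may
#' flag neuromuscular change before the mass-based screening rule does.
#'
#' @param results_t0,results_t1 Data frames as returned by [classify_awgs()],
#'   one row per subject, with a shared `subject_id` column identifying the
#'   same subjects at the two visits.
#' @param model_t0 Optional character vector (or column name in
#'   `results_t0`) of model-predicted classes at baseline
#'   (`"healthy"`/`"sarcopenia"`); used to flag early-detection candidates.
#' @return Tibble with `subject_id`, `class_t0`, `class_t1`, a `transition`
#'   label (`"stable-healthy"`, `"incident-sarcopenia"`,
#'   `"stable-sarcopenia"`, `"recovered"` or `"other"`) and a logical
#'   `early_detection_candidate` column.
#' @export
longitudinal_compare <- function(results_t0, results_t1, model_t0 = NULL) {
  if (!"subject_id" %in% names(results_t0) || !"subject_id" %in% names(results_t1)) {
    abort("both result tables need a `subject_id` column")
  }
  if (!setequal(results_t0$subject_id, results_t1$subject_id)) {
    abort("`results_t0` and `results_t1` must cover the same subjects")
  }
  t0 <- results_t0[match(results_t0$subject_id, results_t0$subject_id), ]
  t1 <- results_t1[match(results_t0$subject_id, results_t1$subject_id), ]

  transition <- dplyr::case_when(
    t0$classification == "healthy" & t1$classification == "healthy" ~ "stable-healthy",
    t0$classification == "healthy" & t1$classification == "sarcopenia" ~ "incident-sarcopenia",
    t0$classification == "sarcopenia" & t1$classification == "sarcopenia" ~ "stable-sarcopenia",
    t0$classification == "sarcopenia" & t1$classification == "healthy" ~ "recovered",
    TRUE ~ "other"
  )

  early <- rep(FALSE, nrow(t0))
  if (!is.null(model_t0)) {
    if (is.character(model_t0) && length(model_t0) == 1L && model_t0 %in% names(results_t0)) {
      model_t0 <- results_t0[[model_t0]]
    }
    early <- t0$classification == "healthy" &
      model_t0 == "sarcopenia" &
      t1$classification == "sarcopenia"
  }

  tibble(
    subject_id = t0$subject_id,
    class_t0 = t0$classification,
    class_t1 = t1$classification,
    transition = transition,
    early_detection_candidate = early
  )
}
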