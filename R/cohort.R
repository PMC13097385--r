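#' Generate a synthetic screening cohort
#'
#' Draws a virtual cohort of elderly subjects (age >= 60) with
#' AWGS-consistent clinical metadata and one full four-channel grip-test
#' recording each. Metadata (sex, grip strength, skeletal muscle index,
#' chair-stand time) are drawn from group- and sex-conditional
#' distributions and accepted only when [classify_awgs()] applied to the
#' drawn values reproduces the intended group label (rejection sampling),
#' so the ground-truth label is consistent with the screening rule by
#' construction.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param prevalence Fraction of sarcopenic subjects in (0, 1).
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole cohort is deterministic in
#'   (`n_subjects`, `prevalence`, `config`, `seed`).
#' @param max_reject Maximum metadata redraws per subject before erroring.
#' @return Tibble with one row per subject: `subject_id`, `sex`, `age`,
#'   `grip_kg`, `smi`, `chair_stand_s`, `group_label`, `seed` (per-subject
#'   session seed) and a `recording` list-column of [generate_session()]
#'   outputs.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_subjects = 4, prevalence = 0.5, seed = 11)
#' cohort$recording[[1]]
#' }
#' @export
generate_cohort <- function(n_subjects = 75, prevalence = 0.4,
                            config = sim_config(), seed = config$seed,
                            max_reject = 1000L) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2")
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must lie in (0, 1)")

  n_sarc <- max(1L, min(n_subjects - 1L, as.integer(round(prevalence * n_subjects))))
  labels <- c(
    rep("sarcopenia", n_sarc),
    rep("healthy", n_subjects - n_sarc)
  )

  set.seed(seed)
  labels <- sample(labels) # interleave groups in subject order
  profiles <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    profiles[[i]] <- draw_profile(labels[i], max_reject = max_reject)
  }
  profiles <- list_rbind(profiles)
  profiles$subject_id <- sprintf("S%03d", seq_len(n_subjects))
  profiles$phenotype <- ifelse(
    profiles$group_label == "sarcopenia",
    sample(names(config$phenotype_mix), n_subjects,
      replace = TRUE, prob = config$phenotype_mix
    ),
    "none"
  )
  profiles$seed <- sapply(seq_len(n_subjects), function(i) derive_seed(seed, 100L + i))

  profiles$recording <- lapply(seq_len(n_subjects), function(i) {
    generate_session(profiles[i, ], config, seed = profiles$seed[i])
  })
  dplyr::relocate(profiles, "subject_id")
}

# group- and sex-conditional metadata distributions (kg, kg/m^2, s), chosen
# around the AWGS cut-offs; rejection sampling enforces label consistency
draw_profile <- function(group_label, max_reject = 1000L) {
  sex <- sample(c("male", "female"), 1L)
  for (tries in seq_len(max_reject)) {
    if (group_label == "healthy") {
      grip <- rnorm(1, if (sex == "male") 32 else 22, if (sex == "male") 3 else 2.5)
      smi <- rnorm(1, if (sex == "male") 7.9 else 6.3, 0.45)
      chair <- rnorm(1, 9, 1.5)
      age <- runif(1, 60, 85)
    } else {
      # grip overlaps the healthy range: part of the sarcopenia group has
      # preserved strength and screens in through chair-stand time instead
      grip <- rnorm(1, if (sex == "male") 26.5 else 16.5, if (sex == "male") 2.5 else 2)
      smi <- rnorm(1, if (sex == "male") 6.3 else 5.1, 0.35)
      chair <- rnorm(1, 13.5, 2)
      age <- runif(1, 63, 90)
    }
    if (grip <= 0 || smi <= 0 || chair <= 0) next
    cand <- tibble(
      sex = sex, age = round(age), grip_kg = grip, smi = smi,
      chair_stand_s = chair, group_label = group_label
    )
    if (classify_awgs(cand)$classification == group_label) {
      cand$grip_strength <- cand$grip_kg
      return(cand)
    }
  }
  abort(sprintf(
    "could not draw AWGS-consistent metadata for group \"%s\" after %d tries",
    group_label, max_reject
  ))
}

#' Write / read a cohort as delimited text plus a JSON manifest
#'
#' One CSV per session (columns `time_s`, `br_semg`, `br_strain`,
#' `fds_semg`, `fds_strain`) and a `manifest.json` holding the per-subject
#' metadata and file names.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a cohort tibble equivalent to the one written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("writing a cohort manifest requires the jsonlite package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    files[i] <- paste0(cohort$subject_id[i], ".csv")
    utils::write.csv(as_tibble(cohort$recording[[i]]),
      file.path(dir, files[i]),
      row.names = FALSE
    )
  }
  manifest <- cohort[, intersect(
    c(
      "subject_id", "sex", "age", "grip_kg", "smi",
      "chair_stand_s", "group_label", "phenotype", "seed"
    ),
    names(cohort)
  )]
  manifest$file <- files
  manifest$trial_boundaries <- lapply(cohort$recording, function(r) {
    unname(apply(r$trial_boundaries, 1, as.integer, simplify = FALSE))
  })
  manifest$sampling_rate <- sapply(cohort$recording, `[[`, "sampling_rate")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("reading a cohort manifest requires the jsonlite package")
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE, simplifyDataFrame = TRUE
  )
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    d <- utils::read.csv(file.path(dir, manifest$file[i]))
    tb <- manifest$trial_boundaries[[i]]
    if (is.list(tb)) tb <- do.call(rbind, lapply(tb, as.integer))
    tb <- matrix(as.integer(tb), ncol = 2,
      dimnames = list(NULL, c("start", "end")))
    structure(
      list(
        channels = list(
          br_semg = d$br_semg, br_strain = d$br_strain,
          fds_semg = d$fds_semg, fds_strain = d$fds_strain
        ),
        sampling_rate = manifest$sampling_rate[i],
        trial_boundaries = tb,
        subject_id = manifest$subject_id[i]
      ),
      class = "recording"
    )
  })
  out <- as_tibble(manifest[, setdiff(names(manifest), c("file", "trial_boundaries", "sampling_rate"))])
  out$grip_strength <- out$grip_kg
  out$recording <- recs
  out
}
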