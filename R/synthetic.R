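# Synthetic study-condition generators: task displays with a minimum angular
# separation, trial-level response errors with per-subject heterogeneity in
# retrieval success and precision, two-timepoint cohort tables with lifestyle
# and covariate structure, and item-level Likert lifestyle responses. All
# generators are pure functions of (config, seed): the same seed reproduces
# the output exactly.

#' Generate task displays with a minimum angular separation
#'
#' Places `objects_per_display` target objects on circular positions for each
#' of `n_scenes` background scenes, rejection-sampling uniform positions in
#' \[0, 360) until all pairwise circular separations within a display are at
#' least `min_separation` (preventing object overlap). Each target slot is
#' paired with a perceptually similar lure for the mnemonic-discrimination
#' stage, so the default configuration of 29 scenes x 3 objects uses 87
#' target/lure pairs, i.e. 174 distinct objects.
#'
#' @param n_scenes Number of displays (default 29).
#' @param objects_per_display Objects per display (default 3).
#' @param min_separation Minimum pairwise circular separation in degrees
#'   (default 62.04).
#' @param seed Optional integer seed.
#' @param max_attempts Rejection-sampling attempts per display before giving
#'   up (default 10000), so configurations that are feasible on paper but
#'   practically unsatisfiable fail loudly.
#' @return A `display_set`: tibble with columns `scene_id`, `slot`,
#'   `position_deg`, `target_object`, `lure_object`, carrying the generating
#'   configuration in the `"config"` attribute.
#' @export
generate_displays <- function(n_scenes = 29, objects_per_display = 3,
                              min_separation = 62.04, seed = NULL,
                              max_attempts = 10000) {
  if (n_scenes < 1 || objects_per_display < 1) {
    stop("`n_scenes` and `objects_per_display` must be >= 1", call. = FALSE)
  }
  if (objects_per_display * min_separation >= 360 && objects_per_display > 1) {
    stop("infeasible configuration: ", objects_per_display, " objects x ",
         min_separation, " deg exceeds the circle", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  positions <- matrix(NA_real_, n_scenes, objects_per_display)
  for (s in seq_len(n_scenes)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      pos <- stats::runif(objects_per_display, 0, 360)
      if (min_circular_separation(pos) >= min_separation) {
        positions[s, ] <- pos
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not satisfy the separation constraint for scene ", s,
           " within ", max_attempts, " attempts", call. = FALSE)
    }
  }
  slots <- n_scenes * objects_per_display
  out <- tibble::tibble(
    scene_id = rep(seq_len(n_scenes), each = objects_per_display),
    slot = rep(seq_len(objects_per_display), times = n_scenes),
    position_deg = as.vector(t(positions)),
    target_object = 2 * seq_len(slots) - 1,
    lure_object = 2 * seq_len(slots)
  )
  attr(out, "config") <- list(n_scenes = n_scenes,
                              objects_per_display = objects_per_display,
                              min_separation = min_separation, seed = seed)
  class(out) <- c("display_set", class(out))
  out
}

min_circular_separation <- function(pos) {
  if (length(pos) < 2) return(Inf)
  d <- abs(outer(pos, pos, "-"))
  d <- pmin(d, 360 - d)
  min(d[upper.tri(d)])
}

#' Default configuration for the two-timepoint cohort generator
#'
#' Population settings emulating an online longitudinal aging cohort:
#' group-level retrieval success around 0.67 and concentration around 15.6
#' (with between-subject spread on the logit and log scales respectively),
#' typical lifestyle scores with mean 33.37 (SD 7.39), pandemic scores with
#' mean 28.90 (SD 7.53) correlated 0.86 with the typical score, and
#' covariates (age, gender, depression, family history of dementia,
#' follow-up interval) with realistic marginals.
#'
#' @param pT_mean Population mean retrieval success (on the probability
#'   scale; converted to a logit-normal location).
#' @param pT_sd_logit Between-subject SD of logit retrieval success.
#' @param kappa_mean Population mean concentration (log-normal location is
#'   `log(kappa_mean)`).
#' @param kappa_sd_log Between-subject SD of log concentration.
#' @param t2_pT_shift Mean T2 shift of logit retrieval success (0 = no true
#'   change).
#' @param t2_kappa_shift Mean T2 shift of log concentration.
#' @param change_sd_logit SD of the subject-specific T2 shift in logit
#'   retrieval success.
#' @param change_sd_log SD of the subject-specific T2 shift in log
#'   concentration.
#' @param lifestyle_memory_r Target correlation between lifestyle change and
#'   the true change in retrieval success / concentration (0 = lifestyle has
#'   no effect on memory change).
#' @param lifestyle_typical_mean,lifestyle_typical_sd Typical lifestyle sum
#'   score distribution.
#' @param lifestyle_pandemic_mean,lifestyle_pandemic_sd Pandemic lifestyle
#'   sum score distribution.
#' @param lifestyle_r Correlation between typical and pandemic scores.
#' @param age_mean,age_sd Age at baseline (years).
#' @param prop_female Proportion female.
#' @param prop_family_history Proportion with a family history of dementia.
#' @param depression_mean,depression_sd Depression score (CESD-R10-like
#'   0-30 scale; draws truncated to it).
#' @param followup_mean,followup_sd Follow-up interval (years), truncated
#'   at 0.5.
#' @param attrition Fraction of subjects missing at T2, missing completely
#'   at random.
#' @return A list of settings for [generate_cohort()].
#' @export
cohort_config <- function(pT_mean = 0.67, pT_sd_logit = 0.6,
                          kappa_mean = 15.63, kappa_sd_log = 0.4,
                          t2_pT_shift = 0, t2_kappa_shift = 0,
                          change_sd_logit = 0.3, change_sd_log = 0.2,
                          lifestyle_memory_r = 0,
                          lifestyle_typical_mean = 33.37,
                          lifestyle_typical_sd = 7.39,
                          lifestyle_pandemic_mean = 28.90,
                          lifestyle_pandemic_sd = 7.53,
                          lifestyle_r = 0.86,
                          age_mean = 70.5, age_sd = 5.7,
                          prop_female = 0.64,
                          prop_family_history = 18 / 59,
                          depression_mean = 7.14, depression_sd = 4.21,
                          followup_mean = 2.76, followup_sd = 0.95,
                          attrition = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$pT_mean > 0, cfg$pT_mean < 1, cfg$kappa_mean > 0,
            cfg$kappa_sd_log >= 0, cfg$pT_sd_logit >= 0,
            abs(cfg$lifestyle_r) < 1, abs(cfg$lifestyle_memory_r) <= 1,
            cfg$attrition >= 0, cfg$attrition < 1)
  cfg
}

#' Generate a two-timepoint cohort with trials, lifestyle and covariates
#'
#' Draws per-subject true mixture parameters (logit-normal retrieval
#' success, log-normal concentration), correlated typical/pandemic lifestyle
#' sum scores, and covariates; shifts each subject's T2 parameters by a
#' subject-specific change that can be coupled to their lifestyle change via
#' `lifestyle_memory_r`; and simulates trial-level response errors from the
#' mixture at both timepoints.
#'
#' The coupling construction: with target correlation `r`, the standardised
#' true memory change is `r * z_lifestyle_change + sqrt(1 - r^2) * noise`,
#' so on the true-parameter scale the lifestyle-change/memory-change
#' correlation equals `r` (estimation noise attenuates it in fitted values).
#'
#' @param n_subjects Number of subjects (default 59).
#' @param trials_per_subject Trials per subject per timepoint (default 75).
#' @param config Settings from [cohort_config()].
#' @param seed Optional integer seed.
#' @param simulate_trials If `FALSE`, skip trial simulation and return only
#'   the cohort table (fast, for design-level checks).
#' @return List with `cohort` (tibble, one row per subject x timepoint,
#'   including true `pT` and `kappa`) and `trials` (tibble with
#'   `subject_id`, `timepoint`, `trial`, `error_deg`; `NULL` when
#'   `simulate_trials = FALSE`).
#' @export
generate_cohort <- function(n_subjects = 59, trials_per_subject = 75,
                            config = cohort_config(), seed = NULL,
                            simulate_trials = TRUE) {
  if (n_subjects < 1 || trials_per_subject < 1) {
    stop("`n_subjects` and `trials_per_subject` must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cfg <- config

  # correlated lifestyle scores (bivariate normal, then bounded below at 0)
  z1 <- stats::rnorm(n_subjects)
  z2 <- cfg$lifestyle_r * z1 +
    sqrt(1 - cfg$lifestyle_r^2) * stats::rnorm(n_subjects)
  lifestyle_typical <- pmax(0, cfg$lifestyle_typical_mean +
                              cfg$lifestyle_typical_sd * z1)
  lifestyle_pandemic <- pmax(0, cfg$lifestyle_pandemic_mean +
                               cfg$lifestyle_pandemic_sd * z2)
  life_change <- lifestyle_typical - lifestyle_pandemic
  z_change <- as.numeric(scale(life_change))
  if (any(!is.finite(z_change))) z_change <- rep(0, n_subjects)

  # true T1 parameters
  logit_pT1 <- stats::qlogis(cfg$pT_mean) +
    cfg$pT_sd_logit * stats::rnorm(n_subjects)
  log_k1 <- log(cfg$kappa_mean) + cfg$kappa_sd_log * stats::rnorm(n_subjects)

  # T2 shifts; more lifestyle decline (larger positive change score) pushes
  # memory change downwards when the coupling is positive
  r <- cfg$lifestyle_memory_r
  mix <- function(noise) r * (-z_change) + sqrt(1 - r^2) * noise
  d_logit <- cfg$t2_pT_shift + cfg$change_sd_logit * mix(stats::rnorm(n_subjects))
  d_log <- cfg$t2_kappa_shift + cfg$change_sd_log * mix(stats::rnorm(n_subjects))
  logit_pT2 <- logit_pT1 + d_logit
  log_k2 <- log_k1 + d_log

  covars <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n_subjects)),
    age = round(stats::rnorm(n_subjects, cfg$age_mean, cfg$age_sd), 1),
    gender = ifelse(stats::runif(n_subjects) < cfg$prop_female,
                    "female", "male"),
    family_history = stats::runif(n_subjects) < cfg$prop_family_history,
    depression = pmin(30, pmax(0, round(
      stats::rnorm(n_subjects, cfg$depression_mean, cfg$depression_sd)))),
    followup_years = pmax(0.5, round(
      stats::rnorm(n_subjects, cfg$followup_mean, cfg$followup_sd), 2)),
    lifestyle_typical = round(lifestyle_typical, 1),
    lifestyle_pandemic = round(lifestyle_pandemic, 1)
  )

  present_t2 <- stats::runif(n_subjects) >= cfg$attrition
  tp_tbl <- function(tp, lp, lk, keep) {
    tibble::tibble(
      subject_id = covars$subject_id[keep],
      timepoint = tp,
      true_pT = stats::plogis(lp[keep]),
      true_kappa = exp(lk[keep])
    )
  }
  cohort <- dplyr::bind_rows(
    tp_tbl("T1", logit_pT1, log_k1, rep(TRUE, n_subjects)),
    tp_tbl("T2", logit_pT2, log_k2, present_t2)
  )
  cohort <- dplyr::left_join(cohort, covars, by = "subject_id")
  cohort <- dplyr::arrange(cohort, .data$subject_id, .data$timepoint)

  trials <- NULL
  if (simulate_trials) {
    trials <- dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
      tibble::tibble(
        subject_id = cohort$subject_id[i],
        timepoint = cohort$timepoint[i],
        trial = seq_len(trials_per_subject),
        error_deg = simulate_errors(trials_per_subject, cohort$true_pT[i],
                                    cohort$true_kappa[i])
      )
    }))
  }
  list(cohort = cohort, trials = trials)
}

#' Generate two-group trial-level data
#'
#' Convenience generator for the two-group (e.g. in-person vs online) design:
#' per-subject true parameters drawn around configurable group-level values,
#' trials simulated from the mixture. Under the default null configuration
#' both groups share the same population.
#'
#' @param n_subjects Subjects per group.
#' @param trials_per_subject Trials per subject.
#' @param pT Group-level retrieval success, length 1 (both groups) or 2.
#' @param kappa Group-level concentration, length 1 or 2.
#' @param pT_sd_logit,kappa_sd_log Between-subject spread.
#' @param groups Group labels (default `"group1"`, `"group2"`).
#' @param seed Optional integer seed.
#' @return Tibble with `subject_id`, `group`, `trial`, `error_deg`,
#'   `true_pT`, `true_kappa`.
#' @export
generate_two_group_trials <- function(n_subjects = 30, trials_per_subject = 75,
                                      pT = 0.7, kappa = 14,
                                      pT_sd_logit = 0.4, kappa_sd_log = 0.3,
                                      groups = c("group1", "group2"),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pT <- rep_len(pT, 2)
  kappa <- rep_len(kappa, 2)
  dplyr::bind_rows(lapply(1:2, function(g) {
    lp <- stats::qlogis(pT[g]) + pT_sd_logit * stats::rnorm(n_subjects)
    lk <- log(kappa[g]) + kappa_sd_log * stats::rnorm(n_subjects)
    dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
      tibble::tibble(
        subject_id = sprintf("%s_s%03d", groups[g], i),
        group = groups[g],
        trial = seq_len(trials_per_subject),
        error_deg = simulate_errors(trials_per_subject, stats::plogis(lp[i]),
                                    exp(lk[i])),
        true_pT = stats::plogis(lp[i]),
        true_kappa = exp(lk[i])
      )
    }))
  }))
}

#' Default item configuration for the lifestyle item generator
#'
#' Seventeen activity items of the kind found in the non-specific section of
#' a lifetime-experiences questionnaire, each with a typical-phase response
#' level and a pandemic shift. The default shifts encode widespread but
#' uneven decline: social, vigorous-physical and leaving-home activities
#' drop most, home-based cognitive activities are maintained.
#'
#' @return Tibble with `item_id`, `typical_mean`, `typical_sd`,
#'   `pandemic_shift`.
#' @export
default_item_config <- function() {
  tibble::tibble(
    item_id = c("socialising_family", "socialising_friends", "social_outings",
                "entertainment_events", "restaurants", "travel_trips",
                "social_groups", "charity_work", "mild_pa", "moderate_pa",
                "vigorous_pa", "reading", "musical_instrument",
                "artistic_pastime", "hobbies", "languages", "courses"),
    typical_mean = c(3.2, 3.4, 2.8, 2.2, 2.6, 1.8, 2.0, 1.4, 3.8, 3.0, 1.8,
                     4.0, 0.8, 1.2, 3.0, 0.8, 0.9),
    typical_sd = rep(1.2, 17),
    pandemic_shift = c(1.2, 1.3, 1.5, 1.6, 1.7, 1.3, 1.1, 0.8, 0.2, 0.4, 0.9,
                       -0.1, 0.1, 0.2, 0.1, 0.0, 0.1)
  )
}

#' Generate item-level Likert lifestyle responses
#'
#' Draws typical-phase responses on the 0-5 frequency scale (0 = never,
#' 5 = daily) from a discretised normal per item, then pandemic responses as
#' the typical response minus the configured per-item shift plus noise,
#' rounded and clipped to the scale.
#'
#' @param n_subjects Number of subjects.
#' @param item_config Tibble as returned by [default_item_config()].
#' @param noise_sd SD of the subject-level noise on the pandemic shift
#'   (default 0.8).
#' @param seed Optional integer seed.
#' @return Tibble with `subject_id`, `item_id`, `phase`
#'   (`"typical"`/`"pandemic"`), `response` in 0-5.
#' @export
generate_lifestyle_items <- function(n_subjects = 59,
                                     item_config = default_item_config(),
                                     noise_sd = 0.8, seed = NULL) {
  if (nrow(item_config) < 1) stop("need at least one item", call. = FALSE)
  if (any(item_config$typical_mean < 0 | item_config$typical_mean > 5)) {
    stop("`typical_mean` must lie in the 0-5 response range", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  subj <- sprintf("s%03d", seq_len(n_subjects))
  rows <- lapply(seq_len(nrow(item_config)), function(j) {
    typ_raw <- stats::rnorm(n_subjects, item_config$typical_mean[j],
                            item_config$typical_sd[j])
    typ <- pmin(5, pmax(0, round(typ_raw)))
    pan_raw <- typ - item_config$pandemic_shift[j] +
      stats::rnorm(n_subjects, 0, noise_sd)
    pan <- pmin(5, pmax(0, round(pan_raw)))
    tibble::tibble(
      subject_id = rep(subj, 2),
      item_id = item_config$item_id[j],
      phase = rep(c("typical", "pandemic"), each = n_subjects),
      response = c(typ, pan)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$subject_id, .data$item_id,
                 dplyr::desc(.data$phase))
}
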