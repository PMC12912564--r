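# Orchestration of the two study shapes: a two-group comparison (test
# environment) and a two-timepoint change analysis (lifestyle change vs
# memory change), with the data-hygiene rules applied throughout: 3-SD
# outlier exclusion per outcome, z-scoring against a reference sample, and
# full accounting of every subject as analysed or excluded.

#' Flag outliers more than a multiple of the SD from the mean
#'
#' Single-pass rule: a value is excluded when `|v - mean| / SD` exceeds
#' `multiplier`, with mean and SD computed once over all values (not
#' iteratively re-estimated after exclusions). A zero-SD (constant) vector
#' excludes nothing, with a warning.
#'
#' @param values Numeric vector of subject-level outcomes (at least 3).
#' @param multiplier SD multiplier (default 3).
#' @return List with `keep` (logical mask), `log` (tibble of excluded
#'   indices, values and z-scores), `mean` and `sd` used.
#' @export
exclude_outliers <- function(values, multiplier = 3) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (multiplier <= 0) stop("`multiplier` must be > 0", call. = FALSE)
  ok <- is.finite(values)
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0) {
    warning("zero SD; no outliers excluded", call. = FALSE)
    return(list(keep = ok, log = empty_exclusion_log(), mean = m, sd = s))
  }
  z <- (values - m) / s
  keep <- ok & abs(z) <= multiplier
  excluded <- which(ok & !keep)
  list(
    keep = keep,
    log = tibble::tibble(index = excluded, value = values[excluded],
                         z = z[excluded],
                         reason = sprintf("|z| = %.2f > %g", abs(z[excluded]),
                                          multiplier)),
    mean = m, sd = s
  )
}

empty_exclusion_log <- function() {
  tibble::tibble(index = integer(), value = numeric(), z = numeric(),
                 reason = character())
}

#' Standardise values against a reference sample
#'
#' Computes z-scores `(v - mean(reference)) / sd(reference)`, so outcomes
#' from different studies can be compared on the scale of the full original
#' sample rather than the analysed subset.
#'
#' @param values Numeric vector to standardise.
#' @param reference Numeric reference sample (its mean and SD define the
#'   scale).
#' @return Numeric vector of z-scores.
#' @export
zscore_by_reference <- function(values, reference) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 2) stop("reference needs at least 2 finite values",
                                  call. = FALSE)
  s <- stats::sd(reference)
  if (!is.finite(s) || s == 0) stop("reference SD is zero", call. = FALSE)
  (values - mean(reference)) / s
}

#' Two-group analysis of a continuous-report experiment
#'
#' Reproduces the shape of a two-group (e.g. in-person vs online) comparison:
#' subject-level mean absolute localisation error and semi-parametric
#' retrieval/precision estimates, group-level mixture fits with bootstrap
#' confidence intervals, a subject-label permutation test on the group-level
#' parameters, and rank tests with JZS Bayes factors on the subject-level
#' outcomes.
#'
#' @param trials Tibble with `subject_id`, `group` (two levels),
#'   `error_deg`.
#' @param B Permutation iterations (default 1000).
#' @param B_boot Bootstrap resamples for group-level CIs (default 1000; use
#'   0 to skip).
#' @param outlier_multiplier SD multiplier for subject-level outlier
#'   exclusion (default 3).
#' @param seed Optional integer seed governing the permutation and bootstrap
#'   resampling.
#' @return List with `subjects` (subject-level outcomes and inclusion
#'   flags), `group_summary` (per-group means/SDs of subject outcomes and
#'   group-level parameter estimates with bootstrap 95% CIs), `permutation`
#'   (a [permutation_group_test()] result), `tests` (subject-level
#'   Mann-Whitney tests with JZS Bayes factors), and `exclusions`.
#' @export
run_experiment1 <- function(trials, B = 1000, B_boot = 1000,
                            outlier_multiplier = 3, seed = NULL) {
  trials <- validate_trials(trials, need_group = TRUE)
  glev <- sort(unique(as.character(trials$group)))
  if (length(glev) != 2) stop("exactly two groups required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  semi <- semiparametric_analysis(trials)
  mae <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject_id, .data$group),
    mae = mean(abs(.data$error_deg)), n_trials = dplyr::n(),
    .groups = "drop"
  )
  subjects <- dplyr::left_join(
    mae,
    semi$subjects[, c("subject_id", "retrieval", "precision", "cutoff")],
    by = "subject_id"
  )

  # outlier masks per outcome, computed within the full subject sample
  exclusions <- list()
  for (oc in c("mae", "retrieval", "precision")) {
    ex <- exclude_outliers(subjects[[oc]], outlier_multiplier)
    subjects[[paste0("include_", oc)]] <- ex$keep
    ex$log$subject_id <- subjects$subject_id[ex$log$index]
    ex$log$outcome <- oc
    exclusions[[oc]] <- ex$log
  }
  exclusion_log <- dplyr::bind_rows(exclusions)

  perm <- permutation_group_test(trials, B = B)

  boot_ci <- NULL
  if (B_boot > 0) {
    boot_ci <- dplyr::bind_rows(lapply(glev, function(g) {
      sub <- trials[trials$group == g, ]
      ids <- unique(sub$subject_id)
      errs_by_subj <- split(sub$error_deg, sub$subject_id, drop = TRUE)
      draws <- matrix(NA_real_, B_boot, 2)
      for (b in seq_len(B_boot)) {
        pick <- sample(ids, replace = TRUE)
        f <- fast_fit(cos(unlist(errs_by_subj[pick], use.names = FALSE) *
                            DEG2RAD),
                      rbind(c(perm$group_fits[[g]]$pT,
                              perm$group_fits[[g]]$kappa), c(0.5, 8)))
        if (!is.null(f)) draws[b, ] <- f$par
      }
      tibble::tibble(
        group = g,
        parameter = c("pT", "kappa"),
        estimate = c(perm$group_fits[[g]]$pT, perm$group_fits[[g]]$kappa),
        ci_lower = apply(draws, 2, stats::quantile, 0.025, na.rm = TRUE),
        ci_upper = apply(draws, 2, stats::quantile, 0.975, na.rm = TRUE)
      )
    }))
  }

  group_summary <- dplyr::bind_rows(lapply(
    c("mae", "retrieval", "precision"),
    function(oc) {
      keep <- subjects[[paste0("include_", oc)]]
      dplyr::summarise(
        dplyr::group_by(subjects[keep, ], .data$group),
        outcome = oc, mean = mean(.data[[oc]], na.rm = TRUE),
        sd = stats::sd(.data[[oc]], na.rm = TRUE), n = dplyr::n(),
        .groups = "drop"
      )
    }
  ))

  tests <- dplyr::bind_rows(lapply(c("mae", "retrieval", "precision"),
                                   function(oc) {
    keep <- subjects[[paste0("include_", oc)]]
    x <- subjects[[oc]][keep & subjects$group == glev[1]]
    y <- subjects[[oc]][keep & subjects$group == glev[2]]
    rt <- rank_tests(x, y, mode = "mann-whitney")
    tstat <- tryCatch(stats::t.test(x, y)$statistic, error = function(e) NA)
    bf <- if (is.finite(tstat)) {
      jzs_ttest_bf(unname(tstat), length(x), length(y))
    } else NULL
    tibble::tibble(
      outcome = oc, W = rt$statistic, p = rt$p,
      bf01 = if (is.null(bf)) NA_real_ else bf$bf01,
      n1 = length(x), n2 = length(y)
    )
  }))

  list(subjects = subjects, group_summary = group_summary,
       group_ci = boot_ci, permutation = perm, tests = tests,
       exclusions = exclusion_log, groups = glev)
}

#' Two-timepoint change analysis with lifestyle correlations
#'
#' The longitudinal core: per-subject mixture fits at each timepoint,
#' z-scoring of the memory outcomes against the T1 full sample (the
#' reference-study convention), per-outcome 3-SD outlier exclusion,
#' T1-minus-T2 difference scores, and lifestyle-change correlations with
#' stretched-beta Bayes factors, overall and within subgroups (family
#' history of dementia; median split on a configurable risk score) at a
#' Bonferroni-adjusted level.
#'
#' Change scores are oriented as decline: memory change is z(T1) - z(T2) and
#' lifestyle change is typical - pandemic, so a positive correlation means
#' greater lifestyle decline accompanies greater memory decline.
#'
#' @param cohort Tibble with one row per subject x timepoint: `subject_id`,
#'   `timepoint` (`"T1"`/`"T2"`), `lifestyle_typical`, `lifestyle_pandemic`,
#'   `family_history`, and the median-split column named by `split_var`.
#' @param trials Tibble with `subject_id`, `timepoint`, `error_deg`.
#' @param method Subject-level estimator: `"mle"` (default) or `"bayes"`.
#' @param split_var Column of `cohort` used for the median-split subgroups
#'   (default `"depression"`).
#' @param outlier_multiplier SD multiplier for outlier exclusion (default 3).
#' @param subgroup_alpha Bonferroni-adjusted level for the subgroup
#'   correlations (default 0.01).
#' @param n_min Minimum trials per subject-timepoint fit.
#' @return List with `subjects` (wide per-subject table with fits, z-scores
#'   and difference scores), `correlations` (overall lifestyle-change vs
#'   memory-change tests with `r`, `df`, `p`, `bf10`, `bf01`), `paired_test`
#'   (typical vs pandemic Wilcoxon + JZS BF), `subgroups` (per-subgroup
#'   correlation tables), and `exclusions` (every dropped subject with a
#'   reason).
#' @export
run_change_analysis <- function(cohort, trials, method = c("mle", "bayes"),
                                split_var = "depression",
                                outlier_multiplier = 3,
                                subgroup_alpha = 0.01, n_min = 20) {
  method <- match.arg(method)
  cohort <- tibble::as_tibble(cohort)
  trials <- tibble::as_tibble(trials)
  need <- c("subject_id", "timepoint", "error_deg")
  if (!all(need %in% names(trials))) {
    stop("`trials` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }

  fit_fun <- if (method == "mle") {
    function(e) fit_mixture_mle(e, n_min = n_min, hessian = FALSE)
  } else {
    function(e) fit_mixture_bayes(e, n_min = n_min)
  }

  fits <- dplyr::bind_rows(lapply(
    split(trials, interaction(trials$subject_id, trials$timepoint,
                              drop = TRUE)),
    function(d) {
      f <- fit_fun(d$error_deg)
      tibble::tibble(subject_id = d$subject_id[1],
                     timepoint = d$timepoint[1],
                     pT = f$pT, kappa = f$kappa, converged = f$converged)
    }
  ))

  exclusions <- list()
  bad_fit <- fits[!fits$converged, c("subject_id", "timepoint")]
  if (nrow(bad_fit) > 0) {
    exclusions$fit <- tibble::tibble(
      subject_id = bad_fit$subject_id,
      reason = paste0("model fit did not converge at ", bad_fit$timepoint)
    )
    fits <- fits[!(fits$subject_id %in% bad_fit$subject_id), ]
  }

  wide <- tidyr::pivot_wider(fits[, c("subject_id", "timepoint", "pT",
                                      "kappa")],
                             names_from = "timepoint",
                             values_from = c("pT", "kappa"))
  has_both <- stats::complete.cases(wide[, c("pT_T1", "pT_T2")])
  if (any(!has_both)) {
    exclusions$timepoint <- tibble::tibble(
      subject_id = wide$subject_id[!has_both],
      reason = "missing a timepoint"
    )
  }
  wide <- wide[has_both, ]

  # z-score against the T1 full sample (all fitted T1 subjects)
  ref_pT <- fits$pT[fits$timepoint == "T1"]
  ref_k <- fits$kappa[fits$timepoint == "T1"]
  wide$z_pT_T1 <- zscore_by_reference(wide$pT_T1, ref_pT)
  wide$z_pT_T2 <- zscore_by_reference(wide$pT_T2, ref_pT)
  wide$z_kappa_T1 <- zscore_by_reference(wide$kappa_T1, ref_k)
  wide$z_kappa_T2 <- zscore_by_reference(wide$kappa_T2, ref_k)
  wide$change_pT <- wide$z_pT_T1 - wide$z_pT_T2
  wide$change_kappa <- wide$z_kappa_T1 - wide$z_kappa_T2

  # outlier rule applied per outcome on the raw subject-level estimates
  for (oc in c("pT", "kappa")) {
    vals <- c(wide[[paste0(oc, "_T1")]], wide[[paste0(oc, "_T2")]])
    ex <- exclude_outliers(vals, outlier_multiplier)
    n <- nrow(wide)
    flagged <- unique(((ex$log$index - 1) %% n) + 1)
    wide[[paste0("include_", oc)]] <- !(seq_len(n) %in% flagged)
    if (length(flagged) > 0) {
      exclusions[[paste0("outlier_", oc)]] <- tibble::tibble(
        subject_id = wide$subject_id[flagged],
        reason = paste0("outlier on ", oc, " (> ", outlier_multiplier,
                        " SD from the mean)")
      )
    }
  }

  subj_info <- unique(cohort[, intersect(
    c("subject_id", "lifestyle_typical", "lifestyle_pandemic",
      "family_history", split_var), names(cohort))])
  wide <- dplyr::left_join(wide, subj_info, by = "subject_id")
  wide$lifestyle_change <- wide$lifestyle_typical - wide$lifestyle_pandemic

  cor_row <- function(d, outcome) {
    x <- d$lifestyle_change
    y <- d[[paste0("change_", outcome)]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 4) {
      return(tibble::tibble(outcome = outcome, n = n, r = NA_real_,
                            df = n - 2, p = NA_real_, bf10 = NA_real_,
                            bf01 = NA_real_))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    bf <- pearson_bf(unname(ct$estimate), n)
    tibble::tibble(outcome = outcome, n = n, r = unname(ct$estimate),
                   df = n - 2, p = ct$p.value, bf10 = bf$bf10,
                   bf01 = bf$bf01)
  }

  correlations <- dplyr::bind_rows(
    cor_row(wide[wide$include_pT, ], "pT"),
    cor_row(wide[wide$include_kappa, ], "kappa")
  )

  # typical vs pandemic paired comparison
  lt <- wide$lifestyle_typical
  lp <- wide$lifestyle_pandemic
  ok <- is.finite(lt) & is.finite(lp)
  paired_test <- NULL
  if (sum(ok) >= 3) {
    rt <- rank_tests(lt[ok], lp[ok], mode = "wilcoxon-signed-rank")
    tstat <- tryCatch(stats::t.test(lt[ok], lp[ok], paired = TRUE)$statistic,
                      error = function(e) NA)
    bf <- if (is.finite(tstat)) jzs_ttest_bf(unname(tstat), sum(ok)) else NULL
    paired_test <- tibble::tibble(
      mean_typical = mean(lt[ok]), mean_pandemic = mean(lp[ok]),
      W = rt$statistic, p = rt$p, degenerate = rt$degenerate,
      bf10 = if (is.null(bf)) NA_real_ else bf$bf10, n = sum(ok)
    )
  }

  subgroups <- NULL
  if ("family_history" %in% names(wide)) {
    fh <- dplyr::bind_rows(lapply(c(TRUE, FALSE), function(v) {
      d <- wide[!is.na(wide$family_history) & wide$family_history == v, ]
      out <- dplyr::bind_rows(cor_row(d[d$include_pT, ], "pT"),
                              cor_row(d[d$include_kappa, ], "kappa"))
      out$subgroup <- paste0("family_history_", ifelse(v, "yes", "no"))
      out
    }))
    subgroups <- fh
  }
  if (split_var %in% names(wide)) {
    med <- stats::median(wide[[split_var]], na.rm = TRUE)
    ms <- dplyr::bind_rows(lapply(c("above", "at_or_below"), function(side) {
      sel <- if (side == "above") wide[[split_var]] > med else
        wide[[split_var]] <= med
      d <- wide[!is.na(sel) & sel, ]
      out <- dplyr::bind_rows(cor_row(d[d$include_pT, ], "pT"),
                              cor_row(d[d$include_kappa, ], "kappa"))
      out$subgroup <- paste0(split_var, "_", side, "_median")
      out
    }))
    subgroups <- dplyr::bind_rows(subgroups, ms)
  }
  if (!is.null(subgroups)) {
    subgroups$significant <- !is.na(subgroups$p) & subgroups$p < subgroup_alpha
    attr(subgroups, "alpha") <- subgroup_alpha
  }

  list(subjects = wide, correlations = correlations,
       paired_test = paired_test, subgroups = subgroups,
       exclusions = dplyr::bind_rows(exclusions))
}
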