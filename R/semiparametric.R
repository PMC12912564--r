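# Semi-parametric fallback estimator: a converged group-level mixture fit
# yields a guessing threshold; subject-level estimates then come from counts
# and spread of the within-threshold errors. Used when subject-level model
# fits fail to converge.

#' Model-derived guessing threshold
#'
#' The absolute error magnitude at which a response is equally likely to have
#' come from the target (von Mises) component as from the uniform guessing
#' component under the fitted group-level mixture, i.e. the |error| where the
#' posterior responsibility of the target component crosses 0.5:
#' `pT * f_vM(theta; kappa) = (1 - pT) / 360`. Beyond this cutoff a response
#' is more likely a random guess than a noisy retrieval. If the von Mises
#' component dominates everywhere (e.g. `pT` close to 1), the threshold is
#' 180 degrees.
#'
#' @param pT Group-level retrieval-success probability, strictly between 0
#'   and 1.
#' @param kappa Group-level von Mises concentration, > 0.
#' @return Cutoff magnitude in degrees, in (0, 180].
#' @examples
#' guessing_threshold(0.5, 2)   # ~65.7 degrees
#' @export
guessing_threshold <- function(pT, kappa) {
  if (!is.numeric(pT) || length(pT) != 1 || !is.finite(pT) || pT <= 0 ||
      pT > 1) {
    stop("`pT` must be in (0, 1]; no threshold exists at pT = 0",
         call. = FALSE)
  }
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) ||
      kappa <= 0) {
    stop("`kappa` must be > 0 (the mixture is degenerate at kappa = 0)",
         call. = FALSE)
  }
  if (pT == 1) return(180)
  i0e <- besselI(kappa, 0, expon.scaled = TRUE)
  cos_ct <- 1 + (log((1 - pT) / pT) + log(i0e)) / kappa
  if (cos_ct <= -1) return(180)
  if (cos_ct >= 1) {
    stop("the guessing component dominates everywhere; no threshold exists ",
         "for pT = ", pT, ", kappa = ", kappa, call. = FALSE)
  }
  acos(cos_ct) * RAD2DEG
}

#' Subject-level estimates from a guessing threshold
#'
#' Retrieval success is the proportion of responses with |error| within the
#' cutoff; precision is the standard deviation of the within-cutoff errors
#' multiplied by minus one, so that higher (less negative) values indicate
#' greater precision. The spread is the linear SD of the signed errors:
#' inside a narrow cutoff it differs negligibly from the circular SD.
#'
#' @param sample An [error_sample()] or numeric vector of signed errors in
#'   degrees.
#' @param cutoff Guessing threshold in degrees, in (0, 180]; typically from
#'   [guessing_threshold()] applied to a group-level fit.
#' @param sd_type `"sample"` (n - 1 denominator, the default) or
#'   `"population"` (n denominator).
#' @return A list with `cutoff`, `retrieval` (proportion within cutoff),
#'   `precision` (minus the SD of within-cutoff errors; `NA` when no
#'   response falls within the cutoff), `n_within`, and `n_trials`.
#' @export
semiparametric_estimates <- function(sample, cutoff,
                                     sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  errors <- as_errors(sample)
  if (length(errors) == 0) stop("empty sample", call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff) ||
      cutoff <= 0 || cutoff > 180) {
    stop("`cutoff` must be in (0, 180]", call. = FALSE)
  }
  within <- abs(errors) <= cutoff
  n_within <- sum(within)
  retrieval <- n_within / length(errors)
  precision <- NA_real_
  if (n_within >= 2) {
    s <- stats::sd(errors[within])
    if (sd_type == "population") s <- s * sqrt((n_within - 1) / n_within)
    precision <- -s
  } else if (n_within == 1) {
    precision <- if (sd_type == "population") 0 else NA_real_
  }
  list(cutoff = cutoff, retrieval = retrieval, precision = precision,
       n_within = n_within, n_trials = length(errors))
}

#' Semi-parametric analysis of a trial table
#'
#' Convenience wrapper for the full fallback route: fit the mixture to the
#' pooled trials of each group, derive a per-group guessing threshold, then
#' compute subject-level retrieval and precision estimates against the
#' threshold of the subject's own group.
#'
#' @param trials Tibble/data frame with columns `subject_id`, `error_deg`,
#'   and optionally `group` (a single implicit group is assumed when absent).
#' @param sd_type Passed to [semiparametric_estimates()].
#' @param n_min Minimum pooled trials per group for the group-level fit.
#' @return A list with `group_fits` (named list of `mixture_fit`),
#'   `thresholds` (named numeric), and `subjects`: a tibble with one row per
#'   subject (`subject_id`, `group`, `method`, `cutoff`, `retrieval`,
#'   `precision`, `n_within`, `n_trials`).
#' @export
semiparametric_analysis <- function(trials, sd_type = "sample", n_min = 20) {
  trials <- validate_trials(trials, need_group = FALSE)
  groups <- split(trials, trials$group)
  group_fits <- lapply(groups, function(g) fit_mixture_mle(g$error_deg,
                                                           n_min = n_min,
                                                           hessian = FALSE))
  thresholds <- vapply(group_fits, function(f) {
    guessing_threshold(min(max(f$pT, 1e-12), 1 - 1e-12), f$kappa)
  }, numeric(1))
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    per_subj <- split(g$error_deg, g$subject_id, drop = TRUE)
    est <- lapply(per_subj, semiparametric_estimates,
                  cutoff = thresholds[[gname]], sd_type = sd_type)
    tibble::tibble(
      subject_id = names(per_subj),
      group = gname,
      method = "semiparametric",
      cutoff = thresholds[[gname]],
      retrieval = vapply(est, `[[`, numeric(1), "retrieval"),
      precision = vapply(est, `[[`, numeric(1), "precision"),
      n_within = vapply(est, `[[`, numeric(1), "n_within"),
      n_trials = vapply(est, `[[`, numeric(1), "n_trials")
    )
  })
  list(group_fits = group_fits, thresholds = thresholds,
       subjects = dplyr::bind_rows(rows))
}
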