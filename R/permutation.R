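# Group-difference inference on group-level mixture parameters by shuffling
# subject labels. Trials travel with their subject: trials within a subject
# are not exchangeable, subjects are.

#' Permutation test for group differences in mixture parameters
#'
#' Fits the retrieval-success mixture to the pooled trials of each of two
#' groups, then builds a null distribution for the group difference in `pT`
#' and `kappa` by shuffling subject-to-group assignments (preserving the
#' original group sizes) and refitting the model to each permuted group.
#'
#' The two-tailed p-value uses absolute differences with an add-one
#' correction, `p = (#\{|permuted| >= |observed|\} + 1) / (B + 1)`, so p can
#' never be exactly zero and ties count against rejection. The z-score
#' standardises the observed difference by the mean and SD of the permutation
#' distribution. Permutation refits use maximum likelihood with a small
#' warm-started set of starting values (the observed group optima plus grid
#' fallbacks), which keeps the resampling fast without changing the fitted
#' optima.
#'
#' @param trials Tibble/data frame of trial-level data with columns
#'   `subject_id`, `group` (exactly two levels), and `error_deg`.
#' @param B Number of permutations (default 1000).
#' @param n_min Minimum pooled trials per group for each fit.
#' @param max_fail_frac Abort if more than this fraction of permutation fits
#'   fail to converge (default 0.05).
#' @return A `permutation_result`: list with `observed` (named vector,
#'   group2 - group1 for `pT` and `kappa`), `group_fits`, `permuted` (tibble
#'   of permuted differences), `p_value`, `z_score`, `B`, and `groups`
#'   (the level order used; differences are second minus first).
#' @examples
#' \donttest{
#' set.seed(1)
#' trials <- generate_two_group_trials(n_subjects = 8, trials_per_subject = 40)
#' permutation_group_test(trials, B = 99)
#' }
#' @export
permutation_group_test <- function(trials, B = 1000, n_min = 20,
                                   max_fail_frac = 0.05) {
  trials <- validate_trials(trials, need_group = TRUE)
  glev <- sort(unique(as.character(trials$group)))
  if (length(glev) != 2) {
    stop("exactly two groups required; found ", length(glev), call. = FALSE)
  }
  if (B < 1) stop("`B` must be >= 1", call. = FALSE)

  subj_group <- unique(trials[, c("subject_id", "group")])
  if (any(duplicated(subj_group$subject_id))) {
    stop("a subject appears in more than one group", call. = FALSE)
  }
  n1 <- sum(subj_group$group == glev[1])
  n2 <- sum(subj_group$group == glev[2])
  if (n1 < 1 || n2 < 1) stop("each group needs at least one subject",
                             call. = FALSE)

  # per-subject precomputed cos(error) blocks; permutations only reshuffle
  # which blocks are concatenated
  cos_by_subj <- lapply(
    split(trials$error_deg, trials$subject_id, drop = TRUE),
    function(e) cos(e * DEG2RAD)
  )
  subj_ids <- names(cos_by_subj)
  group_of <- subj_group$group[match(subj_ids, subj_group$subject_id)]

  obs_fit1 <- fit_mixture_mle(
    trials$error_deg[trials$group == glev[1]], n_min = n_min, hessian = FALSE)
  obs_fit2 <- fit_mixture_mle(
    trials$error_deg[trials$group == glev[2]], n_min = n_min, hessian = FALSE)
  if (!isTRUE(obs_fit1$converged) || !isTRUE(obs_fit2$converged)) {
    stop("observed group-level fit did not converge", call. = FALSE)
  }
  observed <- c(pT = unname(obs_fit2$pT - obs_fit1$pT),
                kappa = unname(obs_fit2$kappa - obs_fit1$kappa))

  perm_starts <- rbind(
    c(obs_fit1$pT, obs_fit1$kappa),
    c(obs_fit2$pT, obs_fit2$kappa),
    c(0.5, 8)
  )

  perm_pT <- numeric(B)
  perm_kappa <- numeric(B)
  n_fail <- 0L
  idx1_size <- n1
  for (b in seq_len(B)) {
    perm <- sample(subj_ids)
    g1_cos <- unlist(cos_by_subj[perm[seq_len(idx1_size)]], use.names = FALSE)
    g2_cos <- unlist(cos_by_subj[perm[(idx1_size + 1):length(perm)]],
                     use.names = FALSE)
    f1 <- fast_fit(g1_cos, perm_starts)
    f2 <- fast_fit(g2_cos, perm_starts)
    if (is.null(f1) || is.null(f2)) {
      n_fail <- n_fail + 1L
      perm_pT[b] <- NA_real_
      perm_kappa[b] <- NA_real_
      next
    }
    perm_pT[b] <- f2$par[1] - f1$par[1]
    perm_kappa[b] <- f2$par[2] - f1$par[2]
  }
  if (n_fail / B > max_fail_frac) {
    stop("permutation fits failed to converge in ", n_fail, " of ", B,
         " iterations", call. = FALSE)
  }

  permuted <- tibble::tibble(pT = perm_pT, kappa = perm_kappa)
  ok <- stats::complete.cases(permuted)
  p_value <- vapply(c("pT", "kappa"), function(par) {
    (sum(abs(permuted[[par]][ok]) >= abs(observed[[par]])) + 1) / (sum(ok) + 1)
  }, numeric(1))
  z_score <- vapply(c("pT", "kappa"), function(par) {
    s <- stats::sd(permuted[[par]][ok])
    if (!is.finite(s) || s == 0) return(NA_real_)
    (observed[[par]] - mean(permuted[[par]][ok])) / s
  }, numeric(1))

  structure(
    list(observed = observed,
         group_fits = stats::setNames(list(obs_fit1, obs_fit2), glev),
         permuted = permuted, p_value = p_value, z_score = z_score,
         B = B, n_failed = n_fail, groups = glev),
    class = "permutation_result"
  )
}

# single warm-started multi-start L-BFGS-B fit on precomputed cos(errors);
# returns NULL when no start converges
fast_fit <- function(cos_err, starts) {
  fn <- function(par) negloglik_grad(par, cos_err)$value
  gr <- function(par) negloglik_grad(par, cos_err)$gradient
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[i, ], fn, gr, method = "L-BFGS-B",
                   lower = c(0, KAPPA_MIN), upper = c(1, KAPPA_MAX),
                   control = list(factr = 1e7, maxit = 200)),
      error = function(e) NULL
    )
    if (is.null(opt) || opt$convergence != 0) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  best
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> groups:", paste(x$groups, collapse = " vs "),
      " B =", x$B, "\n")
  for (par in c("pT", "kappa")) {
    cat(sprintf("  %-6s observed diff = %+.4f  z = %+.3f  p = %.4f\n",
                par, x$observed[[par]], x$z_score[[par]], x$p_value[[par]]))
  }
  invisible(x)
}
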