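test_that("guessing threshold solves the responsibility-0.5 equation", {
  # closed form at pT = 0.5, kappa = 2: cos(cutoff) = log(I0(2)) / 2
  expect_equal(guessing_threshold(0.5, 2),
               acos(log(besselI(2, 0)) / 2) * 180 / pi, tolerance = 1e-10)
  expect_equal(guessing_threshold(0.5, 2), 65.6697, tolerance = 1e-4)
  # at the cutoff the two mixture components have equal density
  ct <- guessing_threshold(0.4, 8)
  expect_equal(0.4 * dvonmises_deg(ct, 8), 0.6 / 360, tolerance = 1e-10)
  # no guessing mass: threshold saturates at 180
  expect_equal(guessing_threshold(1 - 1e-12, 2), 180)
  expect_equal(guessing_threshold(1, 2), 180)
  # sharper target component pulls the threshold in
  cuts <- sapply(c(1, 2, 5, 20, 100), function(k) guessing_threshold(0.6, k))
  expect_true(all(diff(cuts) < 0))
  expect_error(guessing_threshold(0, 5), "pT")
  expect_error(guessing_threshold(0.5, 0), "kappa")
  expect_error(guessing_threshold(1e-4, 0.1), "dominates")
})

test_that("semiparametric estimates count and spread within-cutoff errors", {
  est <- semiparametric_estimates(c(-10, 0, 10), 90)
  expect_equal(est$retrieval, 1)
  expect_equal(est$precision, -10)                    # sample SD
  est_pop <- semiparametric_estimates(c(-10, 0, 10), 90,
                                      sd_type = "population")
  expect_equal(est_pop$precision, -10 * sqrt(2 / 3))  # population SD
  # all outside the cutoff: retrieval 0, precision missing
  est0 <- semiparametric_estimates(c(120, -150, 170), 30)
  expect_equal(est0$retrieval, 0)
  expect_true(is.na(est0$precision))
  # retrieval is non-decreasing in the cutoff
  set.seed(81)
  errs <- simulate_errors(500, 0.6, 8)
  rets <- sapply(c(10, 30, 60, 120, 180), function(ct)
    semiparametric_estimates(errs, ct)$retrieval)
  expect_true(all(diff(rets) >= 0))
  expect_error(semiparametric_estimates(errs, 0), "cutoff")
  expect_error(semiparametric_estimates(errs, 200), "cutoff")
})

test_that("within-cutoff guesses inflate retrieval by (1-pT) * cutoff / 180", {
  set.seed(82)
  pT <- 0.8
  kappa <- 15
  errs <- simulate_errors(1e5, pT, kappa)
  cutoff <- guessing_threshold(pT, kappa)
  est <- semiparametric_estimates(errs, cutoff)
  inflation <- est$retrieval - pT
  # the uniform mass inside the cutoff, up to Monte-Carlo error and the
  # (small) von Mises tail escaping the cutoff
  expect_lt(abs(inflation - (1 - pT) * cutoff / 180), 0.012)
  # exact expectation: pT * F_vM(cutoff) + (1 - pT) * cutoff / 180
  f_within <- integrate(function(x) dvonmises_deg(x, kappa), -cutoff, cutoff,
                        rel.tol = 1e-10)$value
  expect_lt(abs(est$retrieval -
                  (pT * f_within + (1 - pT) * cutoff / 180)), 0.01)
})

test_that("semiparametric subject estimates track the generating parameters", {
  set.seed(83)
  n_subj <- 60
  true_pT <- seq(0.3, 0.95, length.out = n_subj)
  true_k <- exp(rnorm(n_subj, log(14), 0.35))
  trials <- dplyr::bind_rows(lapply(seq_len(n_subj), function(i) {
    tibble::tibble(subject_id = sprintf("s%02d", i), group = "all",
                   error_deg = simulate_errors(75, true_pT[i], true_k[i]))
  }))
  res <- semiparametric_analysis(trials)
  expect_equal(nrow(res$subjects), n_subj)
  ord <- match(sprintf("s%02d", seq_len(n_subj)), res$subjects$subject_id)
  rho <- cor(res$subjects$retrieval[ord], true_pT, method = "spearman")
  expect_gte(rho, 0.8)
  # precision estimates agree in rank with the SD implied by true kappa
  rho_prec <- cor(res$subjects$precision[ord], -k_to_sd(true_k),
                  method = "spearman")
  expect_gte(rho_prec, 0.8)
})
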