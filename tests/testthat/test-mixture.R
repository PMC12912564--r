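test_that("mixture log-likelihood matches independent density oracles", {
  # pure guessing: density is 1/360 per degree regardless of kappa
  errs <- seq(-179, 180, length.out = 100)
  expect_equal(mixture_loglik(errs, 0, 5), -100 * log(360), tolerance = 1e-10)
  expect_equal(mixture_loglik(errs, 0.7, 0), -100 * log(360),
               tolerance = 1e-10)
  # single trial at the target, even mixture, kappa 2:
  # log(0.5 * e^2 / (2 pi I0(2)) * pi/180 + 0.5 / 360) = -5.134357
  expect_equal(mixture_loglik(0, 0.5, 2), -5.134357, tolerance = 1e-5)
  expect_error(mixture_loglik(numeric(0), 0.5, 2), "empty")
  expect_error(mixture_loglik(10, 1.5, 2), "pT")
  expect_error(mixture_loglik(10, 0.5, -1), "kappa")
})

test_that("mixture density integrates to one and is symmetric", {
  for (k in c(0, 1, 10, 100)) {
    mass <- integrate(function(x) dmixture_deg(x, 0.6, k), -180, 180,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
  set.seed(21)
  errs <- runif(300, -179, 179)
  expect_equal(mixture_loglik(errs, 0.55, 7), mixture_loglik(-errs, 0.55, 7),
               tolerance = 1e-10)
})

test_that("MLE beats a brute-force grid and recovers simulation truths", {
  set.seed(31)
  errs <- simulate_errors(200, 0.65, 9)
  fit <- fit_mixture_mle(errs)
  expect_true(fit$converged)
  expect_gte(fit$loglik, grid_loglik_max(errs) - 1e-6)

  # no-memory data: fitted retrieval success collapses
  set.seed(32)
  unif <- runif(5000, -180, 180)
  expect_lte(fit_mixture_mle(unif)$pT, 0.05)

  # recovery at published group-level parameter values
  set.seed(33)
  big <- simulate_errors(10000, 0.73, 13.87)
  fit2 <- fit_mixture_mle(big)
  expect_lt(abs(fit2$pT - 0.73), 0.02)
  expect_lt(abs(fit2$kappa - 13.87) / 13.87, 0.10)
  expect_false(is.null(fit2$se))
  expect_error(fit_mixture_mle(errs[1:5]), "at least")
})

test_that("MLE bias in retrieval success shrinks with sample size", {
  set.seed(41)
  sizes <- c(100, 1000, 10000)
  bias <- sapply(sizes, function(n) {
    mean(replicate(50, {
      abs(fit_mixture_mle(simulate_errors(n, 0.7, 15),
                          hessian = FALSE)$pT - 0.7)
    }))
  })
  expect_true(all(diff(bias) < 0))
})

test_that("no-guessing fit nests inside the mixture and model comparison works", {
  set.seed(51)
  pure <- simulate_errors(2000, 1, 10)
  f1 <- fit_no_guessing(pure)
  expect_lt(abs(f1$kappa - 10) / 10, 0.10)
  expect_equal(f1$pT, 1)
  # grid oracle for the 1-d fit
  kgrid <- exp(seq(log(0.1), log(100), length.out = 2001))
  ll_grid <- sapply(kgrid, function(k) mixture_loglik(pure, 1, k))
  expect_gte(f1$loglik, max(ll_grid) - 1e-6)

  set.seed(52)
  mixed <- simulate_errors(2000, 0.6, 12)
  cmp <- compare_models(mixed)
  expect_true(cmp$available)
  expect_identical(cmp$preferred, "mixture")
  expect_gte(cmp$mixture$loglik, cmp$no_guessing$loglik)
  expect_gt(cmp$delta_aic, 2)

  cmp_pure <- compare_models(pure)
  expect_true(cmp_pure$preferred == "no_guessing" || cmp_pure$delta_aic <= 2)
  expect_gte(cmp_pure$mixture$loglik, cmp_pure$no_guessing$loglik)
})

test_that("simulated errors follow the mixture distribution", {
  set.seed(61)
  tight <- simulate_errors(1000, 1, 5e4)
  expect_true(all(abs(tight) < 5))
  expect_true(all(tight > -180 & tight <= 180))

  set.seed(62)
  guess <- simulate_errors(5000, 0, 3)
  ks <- suppressWarnings(ks.test(guess, "punif", -180, 180))
  expect_gt(ks$p.value, 0.01)

  # analytic CDF oracle: P(|error| <= 30) at pT 0.73, kappa 13.87 = 0.733946
  set.seed(63)
  big <- simulate_errors(1e5, 0.73, 13.87)
  expect_equal(mean(abs(big) <= 30), 0.733946, tolerance = 0.01)
  expect_error(simulate_errors(0, 0.5, 2), "positive")
})

test_that("error_sample validates its contents", {
  es <- error_sample(c(-10, 0, 180), subject = "s1", group = "online")
  expect_s3_class(es, "error_sample")
  expect_equal(mixture_loglik(es, 0, 1), -3 * log(360))
  expect_error(error_sample(c(0, -180)), "wrap")
  expect_error(error_sample(c(0, NA)), "finite")
})

test_that("Bayesian fit agrees with the MLE and flags convergence", {
  set.seed(71)
  errs <- simulate_errors(2000, 0.67, 15.63)
  bf <- fit_mixture_bayes(errs, n_iter = 2500, n_burn = 800)
  ml <- fit_mixture_mle(errs)
  expect_true(bf$converged)
  expect_lt(abs(bf$pT - ml$pT), 0.03)
  expect_lt(abs(bf$kappa - ml$kappa) / ml$kappa, 0.15)
  expect_true(all(bf$rhat < 1.05))
  expect_equal(dim(bf$ci), c(2, 2))
  expect_true(bf$ci[1, "pT"] < bf$pT && bf$pT < bf$ci[2, "pT"])

  set.seed(72)
  unif <- runif(2000, -180, 180)
  bu <- fit_mixture_bayes(unif, n_iter = 2000, n_burn = 800)
  expect_lte(bu$pT, 0.1)
})
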