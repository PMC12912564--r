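# Two-component circular mixture: a von Mises centred on the target (precision
# of successful retrievals) plus a uniform guessing component. Densities are
# expressed per degree (uniform = 1/360) so log-likelihoods are comparable
# across estimators and modules.

#' Bundle response errors with subject and group labels
#'
#' Light container for one subject's (or one pooled group's) signed response
#' errors. Errors must already be wrapped into (-180, 180]; use
#' [wrap_error()] to compute them from target/response angles.
#'
#' @param errors Numeric vector of signed errors in degrees, each in
#'   (-180, 180].
#' @param subject Subject label (scalar).
#' @param group Group or timepoint label (scalar).
#' @return An object of class `error_sample`.
#' @export
error_sample <- function(errors, subject = NA_character_, group = NA_character_) {
  if (!is.numeric(errors)) stop("`errors` must be numeric", call. = FALSE)
  if (any(!is.finite(errors))) stop("errors must be finite", call. = FALSE)
  if (any(errors <= -180 | errors > 180)) {
    stop("errors must lie in (-180, 180]; wrap them with wrap_error()",
         call. = FALSE)
  }
  structure(
    list(errors = as.numeric(errors), subject = subject, group = group),
    class = "error_sample"
  )
}

as_errors <- function(x) {
  if (inherits(x, "error_sample")) x$errors else as.numeric(x)
}

#' @export
print.error_sample <- function(x, ...) {
  cat("<error_sample> subject:", x$subject, " group:", x$group,
      " n =", length(x$errors), "\n")
  invisible(x)
}

#' Von Mises density on the degree scale
#'
#' Density of a von Mises distribution with mean 0 and concentration `kappa`,
#' expressed per degree so that it integrates to 1 over (-180, 180].
#' Evaluated with exponentially scaled Bessel functions, stable up to the
#' concentration cap of 700.
#'
#' @param x Angle(s) in degrees.
#' @param kappa Concentration, >= 0. `kappa = 0` gives the circular uniform
#'   density 1/360.
#' @return Density value(s) per degree.
#' @export
dvonmises_deg <- function(x, kappa) {
  stopifnot(is.numeric(x), length(kappa) == 1, is.finite(kappa), kappa >= 0)
  exp(kappa * (cos(x * DEG2RAD) - 1)) /
    (360 * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Mixture density of the retrieval-success model on the degree scale
#'
#' `pT * dvonmises_deg(x, kappa) + (1 - pT) / 360`: with probability `pT` the
#' memory is retrieved and the error is von Mises distributed around the
#' target; otherwise the response is a uniform random guess.
#'
#' @param x Angle(s) in degrees.
#' @param pT Retrieval-success probability in \[0, 1\].
#' @param kappa Von Mises concentration, >= 0.
#' @return Density value(s) per degree.
#' @export
dmixture_deg <- function(x, pT, kappa) {
  check_params(pT, kappa)
  pT * dvonmises_deg(x, kappa) + (1 - pT) / 360
}

check_params <- function(pT, kappa) {
  if (!is.numeric(pT) || length(pT) != 1 || !is.finite(pT) || pT < 0 || pT > 1) {
    stop("`pT` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) || kappa < 0) {
    stop("`kappa` must be a single finite value >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Log-likelihood of the two-component mixture
#'
#' @param sample An [error_sample()] or numeric vector of signed errors in
#'   degrees.
#' @param pT Retrieval-success probability.
#' @param kappa Von Mises concentration.
#' @return Sum over trials of the log mixture density (per-degree scale).
#' @export
mixture_loglik <- function(sample, pT, kappa) {
  errors <- as_errors(sample)
  if (length(errors) == 0) stop("empty sample", call. = FALSE)
  check_params(pT, kappa)
  sum(log(dmixture_deg(errors, pT, kappa)))
}

# loglik and gradient from precomputed cos(error in radians); used by the
# optimiser so each evaluation is a few vector ops
negloglik_grad <- function(par, cos_err) {
  pT <- par[1]
  kappa <- par[2]
  i0e <- besselI(kappa, 0, expon.scaled = TRUE)
  g <- exp(kappa * (cos_err - 1)) / (360 * i0e)
  # clamp against underflow at extreme kappa so the optimiser sees a finite
  # (if astronomically poor) objective instead of -Inf
  dens <- pmax(pT * g + (1 - pT) / 360, .Machine$double.xmin)
  ratio <- besselI(kappa, 1, expon.scaled = TRUE) / i0e
  dg_dk <- g * (cos_err - ratio)
  list(
    value = -sum(log(dens)),
    gradient = c(-sum((g - 1 / 360) / dens), -sum(pT * dg_dk / dens))
  )
}

default_start_grid <- function(n_pT = 5, n_kappa = 5) {
  as.matrix(expand.grid(
    pT = seq(0.1, 0.9, length.out = n_pT),
    kappa = exp(seq(log(0.5), log(128), length.out = n_kappa))
  ))
}

#' Maximum-likelihood fit of the retrieval-success mixture
#'
#' Fits `(pT, kappa)` by bounded quasi-Newton optimisation (L-BFGS-B with an
#' analytic gradient) from multiple starting points on a pT-by-kappa grid, and
#' returns the best optimum. Multi-start protects against local optima in the
#' two-parameter likelihood surface. `kappa` is searched on \[1e-3, 700\],
#' `pT` on \[0, 1\].
#'
#' @param sample An [error_sample()] or numeric vector of signed errors in
#'   degrees.
#' @param n_min Minimum number of trials required to attempt a fit
#'   (default 20).
#' @param start_grid Matrix of starting values with columns `pT` and `kappa`;
#'   the default is a 5 x 5 grid.
#' @param hessian If `TRUE` (default), return approximate standard errors
#'   from the observed information at the optimum.
#' @return A `mixture_fit` object: list with `pT`, `kappa`, `loglik`,
#'   `converged`, `n_trials`, `method`, and (optionally) `se` with elements
#'   `pT` and `kappa`.
#' @examples
#' set.seed(1)
#' errs <- simulate_errors(500, pT = 0.7, kappa = 10)
#' fit_mixture_mle(errs)
#' @export
fit_mixture_mle <- function(sample, n_min = 20, start_grid = default_start_grid(),
                            hessian = TRUE) {
  errors <- as_errors(sample)
  n <- length(errors)
  if (n < n_min) {
    stop("sample has ", n, " trials; at least ", n_min, " required",
         call. = FALSE)
  }
  cos_err <- cos(errors * DEG2RAD)
  fn <- function(par) negloglik_grad(par, cos_err)$value
  gr <- function(par) negloglik_grad(par, cos_err)$gradient

  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(start_grid))) {
    opt <- tryCatch(
      stats::optim(
        par = start_grid[i, ], fn = fn, gr = gr, method = "L-BFGS-B",
        lower = c(0, KAPPA_MIN), upper = c(1, KAPPA_MAX),
        control = list(factr = 1e4, maxit = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (opt$convergence == 0) any_converged <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(new_mixture_fit(NA_real_, NA_real_, NA_real_, FALSE, n, "mle"))
  }
  se <- NULL
  if (hessian && any_converged) {
    H <- tryCatch(
      stats::optimHess(best$par, fn = fn, gr = gr),
      error = function(e) NULL
    )
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0)) {
        se <- list(pT = sqrt(V[1, 1]), kappa = sqrt(V[2, 2]))
      }
    }
  }
  new_mixture_fit(unname(best$par[1]), unname(best$par[2]), -best$value,
                  any_converged, n, "mle", se = se)
}

new_mixture_fit <- function(pT, kappa, loglik, converged, n_trials, method,
                            se = NULL, extra = list()) {
  structure(
    c(list(pT = pT, kappa = kappa, loglik = loglik, converged = converged,
           n_trials = n_trials, method = method, se = se), extra),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> method:", x$method, "\n")
  cat(sprintf("  pT = %.4f  kappa = %.3f  (SD = %.2f deg)\n",
              x$pT, x$kappa, if (is.finite(x$kappa) && x$kappa > 0)
                k_to_sd(x$kappa) else NA_real_))
  cat(sprintf("  loglik = %.3f  n = %d  converged: %s\n",
              x$loglik, x$n_trials, x$converged))
  invisible(x)
}

#' Maximum-likelihood fit assuming no guessing occurred
#'
#' Single-parameter alternative with the retrieval-success probability fixed
#' at 1: all responses are treated as noisy retrievals and only the von Mises
#' concentration is estimated. Nested within the two-component mixture, so
#' its log-likelihood can never exceed the mixture's.
#'
#' @inheritParams fit_mixture_mle
#' @return A `mixture_fit` with `pT = 1` and `method = "no_guessing"`.
#' @export
fit_no_guessing <- function(sample, n_min = 20) {
  errors <- as_errors(sample)
  n <- length(errors)
  if (n < n_min) {
    stop("sample has ", n, " trials; at least ", n_min, " required",
         call. = FALSE)
  }
  cos_err <- cos(errors * DEG2RAD)
  nll <- function(kappa) negloglik_grad(c(1, kappa), cos_err)$value
  opt <- stats::optimize(nll, interval = c(KAPPA_MIN, KAPPA_MAX), tol = 1e-8)
  new_mixture_fit(1, opt$minimum, -opt$objective, TRUE, n, "no_guessing")
}

#' Compare the mixture model against the no-guessing alternative
#'
#' Fits both models by maximum likelihood and compares them with AIC
#' (`2k - 2 loglik`, k = 2 for the mixture, k = 1 for the no-guessing model).
#' The model with lower AIC is preferred; a difference above 2 is treated as
#' decisive by the usual model-selection convention.
#'
#' @inheritParams fit_mixture_mle
#' @return A list with both fits, their AICs, `delta_aic`
#'   (no-guessing minus mixture) and `preferred` (`"mixture"` or
#'   `"no_guessing"`), or `preferred = NA` with `available = FALSE` when
#'   either fit failed.
#' @export
compare_models <- function(sample, n_min = 20) {
  fit2 <- fit_mixture_mle(sample, n_min = n_min, hessian = FALSE)
  fit1 <- fit_no_guessing(sample, n_min = n_min)
  if (!isTRUE(fit2$converged) || !isTRUE(fit1$converged)) {
    return(list(mixture = fit2, no_guessing = fit1, available = FALSE,
                aic_mixture = NA_real_, aic_no_guessing = NA_real_,
                delta_aic = NA_real_, preferred = NA_character_))
  }
  aic2 <- 2 * 2 - 2 * fit2$loglik
  aic1 <- 2 * 1 - 2 * fit1$loglik
  list(
    mixture = fit2, no_guessing = fit1, available = TRUE,
    aic_mixture = aic2, aic_no_guessing = aic1,
    delta_aic = aic1 - aic2,
    preferred = if (aic2 < aic1) "mixture" else "no_guessing"
  )
}

#' Simulate response errors from the retrieval-success mixture
#'
#' Each trial is a retrieval with probability `pT`, in which case the error
#' is drawn from a von Mises distribution with mean 0 and concentration
#' `kappa` (Best-Fisher rejection sampling); otherwise the response is a
#' uniform guess on (-180, 180].
#'
#' @param n Number of trials, >= 1.
#' @param pT Retrieval-success probability.
#' @param kappa Von Mises concentration.
#' @return Numeric vector of `n` signed errors in degrees.
#' @export
simulate_errors <- function(n, pT, kappa) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  check_params(pT, kappa)
  retrieved <- stats::runif(n) < pT
  out <- numeric(n)
  n_guess <- sum(!retrieved)
  if (n_guess > 0) out[!retrieved] <- stats::runif(n_guess, -180, 180)
  n_ret <- sum(retrieved)
  if (n_ret > 0) out[retrieved] <- rvonmises_deg(n_ret, kappa)
  # map the open boundary onto the positive side
  out[out <= -180] <- 180
  out
}

# Best & Fisher (1979) wrapped-Cauchy envelope sampler, mean 0, degrees out
rvonmises_deg <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -180, 180))
  if (kappa > 5e5) return(stats::rnorm(n, 0, 1 / sqrt(kappa)) * RAD2DEG)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    accept <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(accept)
    if (k > 0) {
      u3 <- stats::runif(k)
      theta <- sign(u3 - 0.5) * acos(f[accept])
      out[(filled + 1):(filled + k)] <- theta
      filled <- filled + k
    }
  }
  out * RAD2DEG
}
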