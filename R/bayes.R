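# Bayes factors for t-tests (Jeffreys-Zellner-Siow Cauchy prior) and Pearson
# correlations (stretched beta prior), plus the frequentist rank tests used
# alongside them. All alternatives are two-sided.

new_bayes_factor <- function(bf10, method, prior) {
  if (!is.finite(bf10) || bf10 <= 0) {
    stop("Bayes factor computation failed (bf10 = ", bf10, ")", call. = FALSE)
  }
  structure(list(bf10 = bf10, bf01 = 1 / bf10, method = method, prior = prior),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("<bayes_factor> %s  BF10 = %.4g  BF01 = %.4g  (%s)\n",
              x$method, x$bf10, x$bf01, x$prior))
  invisible(x)
}

#' Jeffreys-Zellner-Siow Bayes factor for a t-test
#'
#' Default Bayes factor for a one-sample/paired or two-sample t-test under a
#' Cauchy prior with scale `prior_r` on the standardised effect size (the
#' JZS prior). Computed by adaptive quadrature of the marginal likelihood
#' over the Zellner g-parameter, which carries an inverse-gamma(1/2,
#' `prior_r`^2/2) prior.
#'
#' @param t Observed t-statistic.
#' @param n1 Sample size (first group, or the single sample for a
#'   one-sample/paired test).
#' @param n2 Second group size, or `NULL` for a one-sample/paired test.
#' @param prior_r Cauchy prior scale (default 0.707, i.e. sqrt(2)/2).
#' @return A `bayes_factor` object with fields `bf10` and `bf01`.
#' @examples
#' jzs_ttest_bf(2.0, 30, 30)
#' @export
jzs_ttest_bf <- function(t, n1, n2 = NULL, prior_r = 0.707) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t)) {
    stop("`t` must be a single finite value", call. = FALSE)
  }
  if (is.null(n2)) {
    if (n1 < 3) stop("need n1 >= 3 for a one-sample test", call. = FALSE)
    N <- n1
    df <- n1 - 1
  } else {
    if (n1 < 2 || n2 < 2 || n1 + n2 < 5) {
      stop("need at least 2 per group and 5 in total", call. = FALSE)
    }
    N <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
  }
  null_lik <- (1 + t^2 / df)^(-(df + 1) / 2)
  integrand <- function(g) {
    (1 + N * g)^(-0.5) *
      (1 + t^2 / ((1 + N * g) * df))^(-(df + 1) / 2) *
      prior_r / sqrt(2 * pi) * g^(-1.5) * exp(-prior_r^2 / (2 * g))
  }
  marg <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)
  new_bayes_factor(marg$value / null_lik, "jzs_ttest",
                   sprintf("Cauchy(0, %.3f) on effect size", prior_r))
}

# Gauss hypergeometric 2F1 by power series with an Euler integral fallback
# for slowly converging arguments; only needed on [0, 1)
hyperg_2f1 <- function(a, b, cc, x, max_terms = 8000, tol = 1e-14) {
  if (x == 0) return(1)
  term <- 1
  s <- 1
  for (k in seq_len(max_terms)) {
    term <- term * (a + k - 1) * (b + k - 1) / ((cc + k - 1) * k) * x
    s <- s + term
    if (abs(term) < tol * abs(s)) return(s)
  }
  # Euler integral representation, valid for cc > b > 0
  f <- stats::integrate(
    function(tt) tt^(b - 1) * (1 - tt)^(cc - b - 1) * (1 - x * tt)^(-a),
    0, 1, rel.tol = 1e-10
  )
  exp(lgamma(cc) - lgamma(b) - lgamma(cc - b)) * f$value
}

#' Bayes factor for a Pearson correlation under a stretched beta prior
#'
#' Two-sided default Bayes factor for a Pearson correlation, with a stretched
#' beta prior of width `prior_width` on the population correlation rho: a
#' Beta(1/width, 1/width) distribution stretched to (-1, 1). Width 1 is the
#' uniform prior, under which all correlations in (-1, 1) are equally likely.
#' Uses the closed-form expression in terms of the Gauss hypergeometric
#' function, which depends on the data only through `(n, r)`.
#'
#' @param r Sample Pearson correlation, with |r| < 1.
#' @param n Number of complete pairs, >= 4.
#' @param prior_width Stretched beta prior width (default 1).
#' @return A `bayes_factor` object.
#' @examples
#' pearson_bf(0.082, 54)   # BF01 ~ 5, evidence for the null
#' @export
pearson_bf <- function(r, n, prior_width = 1) {
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || abs(r) >= 1) {
    stop("`r` must satisfy |r| < 1 (|r| = 1 is degenerate)", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || n < 4) {
    stop("`n` must be >= 4", call. = FALSE)
  }
  if (!is.numeric(prior_width) || length(prior_width) != 1 ||
      prior_width <= 0 || prior_width > 2) {
    stop("`prior_width` must be in (0, 2]", call. = FALSE)
  }
  alpha <- 1 / prior_width
  # two-sided BF10; reduces to sqrt(pi)/2 * Gamma((n+1)/2)/Gamma((n+2)/2)
  # * 2F1((n-1)/2, (n-1)/2; (n+2)/2; r^2) when the prior is uniform
  log_const <- (1 - 2 * alpha) * log(2) + 0.5 * log(pi) -
    lbeta(alpha, alpha) +
    lgamma((n + 2 * alpha - 1) / 2) - lgamma((n + 2 * alpha) / 2)
  bf10 <- exp(log_const) *
    hyperg_2f1((n - 1) / 2, (n - 1) / 2, (n + 2 * alpha) / 2, r^2)
  new_bayes_factor(bf10, "pearson_correlation",
                   sprintf("stretched beta, width %.3g", prior_width))
}

#' Rank-based two-sample and paired tests
#'
#' Thin wrapper around [stats::wilcox.test()] providing the Mann-Whitney
#' (independent samples) and Wilcoxon signed-rank (paired) tests with
#' two-tailed p-values, plus explicit handling of the degenerate all-tied
#' paired case, which yields no nonzero differences and therefore no test.
#'
#' @param x Numeric vector.
#' @param y Numeric vector (second group, or paired partner of `x`).
#' @param mode `"mann-whitney"` or `"wilcoxon-signed-rank"`.
#' @return List with `statistic` (U or W), `p`, `mode`, and `degenerate`
#'   (`TRUE` when a paired test had no nonzero differences; `p` is then
#'   `NA`).
#' @export
rank_tests <- function(x, y, mode = c("mann-whitney", "wilcoxon-signed-rank")) {
  mode <- match.arg(mode)
  if (mode == "mann-whitney") {
    if (length(x) < 1 || length(y) < 1) stop("empty group", call. = FALSE)
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    return(list(statistic = unname(wt$statistic), p = wt$p.value,
                mode = mode, degenerate = FALSE))
  }
  if (length(x) != length(y)) stop("paired vectors must match in length",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, mode = mode,
                degenerate = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = "two.sided")
  )
  list(statistic = unname(wt$statistic), p = wt$p.value, mode = mode,
       degenerate = FALSE)
}
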