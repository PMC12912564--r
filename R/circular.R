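# Angle conventions and the circular-SD <-> von Mises concentration mapping.
# All public interfaces use degrees; internal computation is in radians.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

# kappa above this is treated as the overflow cap for the inverse mapping
KAPPA_MAX <- 700
KAPPA_MIN <- 1e-3

#' Signed angular error between a target and a response
#'
#' Computes `response - target` modulo 360 and maps the result into the signed
#' interval (-180, 180]. The +180 boundary is assigned to the positive side,
#' so an error of exactly half a turn is reported as +180.
#'
#' @param target Target angle(s) in degrees. Any real value is accepted and
#'   wrapped.
#' @param response Response angle(s) in degrees.
#' @return Signed error(s) in degrees, in (-180, 180]. Vectorised with the
#'   usual recycling rules.
#' @examples
#' wrap_error(10, 350)   # -20
#' wrap_error(350, 10)   # +20
#' wrap_error(0, 180)    # +180 by convention
#' @export
wrap_error <- function(target, response) {
  if (!is.numeric(target) || !is.numeric(response)) {
    stop("`target` and `response` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(target)) || any(!is.finite(response))) {
    stop("angles must be finite", call. = FALSE)
  }
  err <- (response - target) %% 360
  ifelse(err > 180, err - 360, err)
}

#' Wrap arbitrary angles into the signed error interval
#'
#' @param x Angle(s) in degrees.
#' @return Angle(s) mapped into (-180, 180].
#' @export
wrap_angle <- function(x) {
  wrap_error(0, x)
}

# exponentially scaled Bessel ratio I1(k)/I0(k); the exp(-k) scaling cancels
bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Convert von Mises concentration to circular standard deviation
#'
#' The circular standard deviation of a von Mises distribution with
#' concentration `kappa` is `sqrt(-2 * log(R))` radians, where
#' `R = I1(kappa) / I0(kappa)` is the mean resultant length and `I0`, `I1`
#' are modified Bessel functions of the first kind. Bessel ratios are
#' evaluated with exponentially scaled Bessel functions so large `kappa`
#' does not overflow. The mapping is strictly decreasing: higher
#' concentration means tighter errors.
#'
#' @param kappa Concentration parameter(s), strictly positive.
#' @return Circular standard deviation(s) in degrees.
#' @seealso [sd_to_k()] for the inverse mapping.
#' @examples
#' k_to_sd(2)    # ~48.61 degrees
#' @export
k_to_sd <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa <= 0)) {
    stop("`kappa` must be finite and > 0", call. = FALSE)
  }
  sqrt(-2 * log(bessel_ratio(kappa))) * RAD2DEG
}

#' Convert circular standard deviation to von Mises concentration
#'
#' Numerically inverts [k_to_sd()] by bracketed root finding on `log(kappa)`
#' (the mapping is strictly monotone), rather than using a series
#' approximation, so the round trip `k_to_sd(sd_to_k(x))` is exact to within
#' the solver tolerance (relative tolerance below 1e-8). Solutions above the
#' overflow cap of 700 are truncated there with a warning; a standard
#' deviation so large that the implied concentration underflows returns 0
#' with a warning.
#'
#' @param sd Circular standard deviation(s) in degrees, strictly positive.
#' @return Concentration parameter(s) `kappa`.
#' @examples
#' sd_to_k(48.61)   # ~2.0
#' @export
sd_to_k <- function(sd) {
  if (!is.numeric(sd) || any(!is.finite(sd)) || any(sd <= 0)) {
    stop("`sd` must be finite and > 0", call. = FALSE)
  }
  vapply(sd, sd_to_k_scalar, numeric(1))
}

sd_to_k_scalar <- function(sd) {
  lo <- 1e-8
  hi <- KAPPA_MAX
  if (sd <= k_to_sd(hi)) {
    warning("sd below the resolution of the kappa cap; returning kappa = ",
            KAPPA_MAX, call. = FALSE)
    return(KAPPA_MAX)
  }
  if (sd >= k_to_sd(lo)) {
    warning("sd implies kappa below the numeric floor; returning 0",
            call. = FALSE)
    return(0)
  }
  root <- stats::uniroot(
    function(lk) k_to_sd(exp(lk)) - sd,
    lower = log(lo), upper = log(hi),
    tol = 1e-12
  )
  exp(root$root)
}
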