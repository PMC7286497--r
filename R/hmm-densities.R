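# Emission log-densities and the von Mises CDF used by pseudo-residuals.

#' Gamma log-density in mean/sd parameterization
#'
#' `log f(x; shape = (mean/sd)^2, rate = mean/sd^2)`. Non-positive `x` is not
#' a valid gamma observation; in the likelihood such values are treated as
#' missing (see [fit_hmm()]), here they return `-Inf`.
#'
#' @param x Step length(s), meters.
#' @param mean,sd Gamma mean and standard deviation (> 0).
#' @return Log-density value(s).
#' @export
gamma_logpdf <- function(x, mean, sd) {
  stopifnot(mean > 0, sd > 0)
  dgamma(x, shape = (mean / sd)^2, rate = mean / sd^2, log = TRUE)
}

#' von Mises log-density
#'
#' `log[ exp(kappa * cos(theta - mu)) / (2 * pi * I0(kappa)) ]`, evaluated via
#' the exponentially scaled Bessel function so large kappa stays finite.
#'
#' @param theta Angle(s), radians in `(-pi, pi]`.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, >= 0.
#' @return Log-density value(s).
#' @export
vonmises_logpdf <- function(theta, mu, kappa) {
  stopifnot(kappa >= 0)
  # log I0(kappa) = log(besselI(kappa, 0, scaled)) + kappa
  kappa * cos(theta - mu) - log(2 * pi) -
    (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

#' von Mises cumulative distribution function
#'
#' `P(Theta <= theta)` for Theta on the support `(-pi, pi]`, computed with the
#' standard Bessel Fourier series. Used to build angle pseudo-residuals.
#'
#' @param theta Angle(s), radians in `[-pi, pi]`.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, >= 0.
#' @param n_terms Number of series terms (default scales with kappa).
#' @return CDF value(s) in `[0, 1]`.
#' @export
vonmises_cdf <- function(theta, mu, kappa, n_terms = NULL) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return((theta + pi) / (2 * pi))
  if (is.null(n_terms))
    n_terms <- min(1000L, max(50L, ceiling(4 * sqrt(kappa) * 3)))
  # H(x) = integral of the zero-centered density from -pi to x, x in [-pi, pi]
  j <- seq_len(n_terms)
  ratios <- besselI(kappa, 0:n_terms, expon.scaled = TRUE)
  coef <- ratios[-1] / (ratios[1] * j)
  H <- function(x) {
    sx <- outer(x, j, function(xx, jj) sin(jj * xx))
    (x + pi) / (2 * pi) + as.vector(sx %*% coef) / pi
  }
  xs <- wrap_angle(theta - mu)
  cut <- wrap_angle(-pi - mu)      # image of the support cut -pi
  # mass from the cut going counterclockwise to xs; when xs sits before the
  # cut on (-pi, pi] the integral wraps once around the circle
  out <- H(xs) - H(cut) + (xs < cut)
  out[theta >= pi] <- 1   # wrap_angle identifies pi with -pi; pi closes the support
  pmin(1, pmax(0, out))
}
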