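# Gaussian diffusion-approximation baseline.  In the small-amplitude,
# high-rate limit the synaptic input is characterized by its mean mu_T and
# intensity sigma^2 alone; the amplitude distribution shape is irrelevant.
# The classic quadrature forms are used, written in terms of the scaled
# complementary error function so no e^{x^2} factor is ever formed:
# e^{x^2}(1 + erf(x)) = erfcx(-x).

#' Diffusion-approximation firing rate
#'
#' \eqn{1/r_0 = \tau\sqrt\pi \int_{y_r}^{y_\theta} e^{x^2}(1+erf(x))\,dx}
#' with \eqn{y_\theta = (v_{th}-\mu_T)/\sigma}, \eqn{y_r = (v_{re}-\mu_T)/\sigma}.
#'
#' @param mu_T effective mean input (mV).
#' @param sigma2 noise intensity (mV^2), `> 0`.
#' @param neuron a [lif_neuron()].
#' @return firing rate (Hz).
#' @examples
#' da_rate(9, 2)    # ~12.07 Hz
#' @export
da_rate <- function(mu_T, sigma2, neuron = lif_neuron()) {
  stopifnot(sigma2 > 0)
  s <- sqrt(sigma2)
  yth <- (neuron$v_th - mu_T) / s
  yr <- (neuron$v_re - mu_T) / s
  I <- stats::integrate(function(x) erfcx_safe(-x), yr, yth,
                        rel.tol = 1e-12)$value
  1000 / (neuron$tau * sqrt(pi) * I)
}

#' Diffusion-approximation coefficient of variation
#'
#' \eqn{CV^2 = 2\pi (r_0\tau)^2 \int_{y_r}^{y_\theta} dx\, e^{x^2}
#' \int_{-\infty}^{x} dy\, e^{y^2}(1+erf(y))^2}.  The inner integrand is
#' evaluated as \eqn{erfcx(-y)^2 e^{-y^2}}, which is finite everywhere.
#'
#' @inheritParams da_rate
#' @return the CV (dimensionless).
#' @examples
#' da_cv(9, 2)      # ~0.639
#' @export
da_cv <- function(mu_T, sigma2, neuron = lif_neuron()) {
  stopifnot(sigma2 > 0)
  s <- sqrt(sigma2)
  yth <- (neuron$v_th - mu_T) / s
  yr <- (neuron$v_re - mu_T) / s
  r0 <- da_rate(mu_T, sigma2, neuron) / 1000
  inner <- function(x) vapply(x, function(xx)
    stats::integrate(function(y) erfcx_safe(-y)^2 * exp(-y^2), -Inf, xx,
                     rel.tol = 1e-11)$value, numeric(1))
  I <- stats::integrate(function(x) exp(x^2) * inner(x), yr, yth,
                        rel.tol = 1e-9)$value
  sqrt(2 * pi * (r0 * neuron$tau)^2 * I)
}
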