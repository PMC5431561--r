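# Synaptic amplitude distributions A(a) and their Laplace kernels.
#
# Each distribution object carries closed-form moments, a sampler, a density,
# and the Laplace kernel Q(s) such that the transformed synaptic flux is
# J~(s) = P~(s) Q(s).  For a Poisson train of rate R (kicks/ms) with i.i.d.
# amplitudes a ~ A, the kernel is Q(s) = R (A~(s) - 1)/s where
# A~(s) = E[e^{s a}] is the bilateral Laplace transform of the density.

new_amp_dist <- function(subclass, ...) {
  structure(list(...), class = c(subclass, "amp_dist"))
}

#' Synaptic amplitude distributions
#'
#' Constructors for the amplitude laws of instantaneous post-synaptic
#' potentials: a point mass (`amp_delta`), a one-sided exponential
#' (`amp_exponential`), a uniform law (`amp_uniform`) and a Gaussian truncated
#' to non-positive support (`amp_tgauss`).  Inhibitory laws have support on
#' \eqn{a \le 0}; the exponential law with positive mean is the excitatory
#' EPSP law used with shot-noise drive.
#'
#' For the truncated Gaussian, `a_p` is the peak and `sigma_g` the width of
#' the *untruncated* Gaussian; the distribution is its restriction to
#' \eqn{(-\infty, 0]}.  Its mean is \eqn{a_p - \sigma_G^2 \varphi(0)/\Phi(0)}
#' and its variance
#' \eqn{\sigma_G^2(1 + a_p \varphi(0)/\Phi(0) - (\sigma_G \varphi(0)/\Phi(0))^2)},
#' the standard upper-truncated-normal expressions.
#'
#' @param a point-mass amplitude (mV), negative for inhibition.
#' @param mean mean amplitude (mV); its sign selects the excitatory
#'   (`mean > 0`) or inhibitory (`mean < 0`) exponential branch.
#' @param l1,l2 support endpoints (mV), `l1 < l2 <= 0`.
#' @param a_p peak of the untruncated Gaussian (mV), `a_p < 0`.
#' @param sigma_g width of the untruncated Gaussian (mV), `> 0`.
#' @return an object of class `amp_dist`.
#' @examples
#' amp_moments(amp_delta(-1))
#' amp_moments(amp_tgauss(-0.7766, 0.7766))  # mean ~ -1 mV, sd ~ 0.616 mV
#' @seealso [amp_moments()], [amp_sample()], [amp_kernel_Q()]
#' @export
amp_delta <- function(a) {
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a))
  new_amp_dist("amp_delta", a = a)
}

#' @rdname amp_delta
#' @export
amp_exponential <- function(mean) {
  stopifnot(is.numeric(mean), length(mean) == 1, is.finite(mean), mean != 0)
  new_amp_dist("amp_exponential", scale = abs(mean), sign = sign(mean))
}

#' @rdname amp_delta
#' @export
amp_uniform <- function(l1, l2) {
  stopifnot(is.numeric(l1), is.numeric(l2), l1 < l2)
  if (l2 > 0) stop("uniform amplitude law must have support l1 < l2 <= 0")
  new_amp_dist("amp_uniform", l1 = l1, l2 = l2)
}

#' @rdname amp_delta
#' @export
amp_tgauss <- function(a_p, sigma_g) {
  stopifnot(is.numeric(a_p), is.numeric(sigma_g), sigma_g > 0)
  if (a_p > 0) stop("truncated-Gaussian peak a_p must be <= 0")
  # beta: standardized truncation point; lam: inverse Mills ratio phi/Phi
  beta <- -a_p / sigma_g
  lam <- exp(dnorm(beta, log = TRUE) - pnorm(beta, log.p = TRUE))
  new_amp_dist("amp_tgauss", a_p = a_p, sigma_g = sigma_g,
               beta = beta, lam = lam)
}

#' @export
print.amp_dist <- function(x, ...) {
  m <- amp_moments(x)
  cat(format(x), "\n")
  cat(sprintf("  mean %.4g mV, sd %.4g mV, skewness %.4g\n",
              m$mean, sqrt(m$var), m$skewness))
  invisible(x)
}

#' @export
format.amp_delta <- function(x, ...) sprintf("delta amplitude (a = %g mV)", x$a)
#' @export
format.amp_exponential <- function(x, ...)
  sprintf("exponential amplitude (mean = %g mV, %s)", x$sign * x$scale,
          if (x$sign > 0) "excitatory" else "inhibitory")
#' @export
format.amp_uniform <- function(x, ...)
  sprintf("uniform amplitude on [%g, %g] mV", x$l1, x$l2)
#' @export
format.amp_tgauss <- function(x, ...)
  sprintf("truncated Gaussian amplitude (a_p = %g mV, sigma_G = %g mV)",
          x$a_p, x$sigma_g)

#' Moments of an amplitude distribution
#'
#' Closed-form mean, variance and skewness.  For the truncated Gaussian the
#' third standardized moment is computed from the truncated-normal raw-moment
#' recursion \eqn{m_n = (n-1) m_{n-2} - \beta^{n-1}\lambda} for the
#' standardized variable conditioned on \eqn{Z \le \beta}, with
#' \eqn{\lambda = \varphi(\beta)/\Phi(\beta)}.
#'
#' @param dist an [amp_dist][amp_delta] object.
#' @return list with `mean` (mV), `var` (mV^2), `skewness`, and the raw
#'   second and third moments `m2`, `m3` used by the Laplace engine.
#' @export
amp_moments <- function(dist) UseMethod("amp_moments")

#' @export
amp_moments.amp_delta <- function(dist) {
  a <- dist$a
  list(mean = a, var = 0, skewness = 0, m2 = a^2, m3 = a^3)
}

#' @export
amp_moments.amp_exponential <- function(dist) {
  m <- dist$sign * dist$scale
  list(mean = m, var = dist$scale^2, skewness = 2 * dist$sign,
       m2 = 2 * dist$scale^2, m3 = dist$sign * 6 * dist$scale^3)
}

#' @export
amp_moments.amp_uniform <- function(dist) {
  l1 <- dist$l1; l2 <- dist$l2
  m <- (l1 + l2) / 2
  v <- (l2 - l1)^2 / 12
  m2 <- (l1^2 + l1 * l2 + l2^2) / 3
  m3 <- (l1 + l2) * (l1^2 + l2^2) / 4
  list(mean = m, var = v, skewness = 0, m2 = m2, m3 = m3)
}

#' @export
amp_moments.amp_tgauss <- function(dist) {
  b <- dist$beta; lam <- dist$lam; s <- dist$sigma_g; mu <- dist$a_p
  # standardized conditional moments of Z | Z <= b  (upper truncation)
  z1 <- -lam
  z2 <- 1 - b * lam
  z3 <- -(2 + b^2) * lam
  m1 <- mu + s * z1
  m2 <- mu^2 + 2 * mu * s * z1 + s^2 * z2
  m3 <- mu^3 + 3 * mu^2 * s * z1 + 3 * mu * s^2 * z2 + s^3 * z3
  v <- m2 - m1^2
  c3 <- m3 - 3 * m1 * v - m1^3
  list(mean = m1, var = v, skewness = c3 / v^1.5, m2 = m2, m3 = m3)
}

#' Sample synaptic amplitudes
#'
#' Draws `n` i.i.d. amplitudes.  The truncated Gaussian is sampled by
#' rejection from the untruncated Gaussian (acceptance probability
#' \eqn{\Phi(0) \ge 1/2} for \eqn{a_p \le 0}).  Uses the R random stream;
#' seed with [set.seed()].
#'
#' @param dist an [amp_dist][amp_delta] object.
#' @param n number of draws.
#' @return numeric vector of length `n` (mV).
#' @export
amp_sample <- function(dist, n) UseMethod("amp_sample")

#' @export
amp_sample.amp_delta <- function(dist, n) rep(dist$a, n)

#' @export
amp_sample.amp_exponential <- function(dist, n)
  dist$sign * stats::rexp(n, rate = 1 / dist$scale)

#' @export
amp_sample.amp_uniform <- function(dist, n) stats::runif(n, dist$l1, dist$l2)

#' @export
amp_sample.amp_tgauss <- function(dist, n) {
  out <- numeric(0)
  need <- n
  while (need > 0) {
    m <- ceiling(need / pnorm(dist$beta) * 1.1) + 8
    x <- stats::rnorm(m, dist$a_p, dist$sigma_g)
    x <- x[x <= 0]
    out <- c(out, x[seq_len(min(need, length(x)))])
    need <- n - length(out)
  }
  out
}

#' Amplitude probability density
#'
#' @param dist an [amp_dist][amp_delta] object.
#' @param a evaluation points (mV).
#' @return density values; the delta law returns an error (it has no density).
#' @export
amp_density <- function(dist, a) UseMethod("amp_density")

#' @export
amp_density.amp_delta <- function(dist, a)
  stop("the delta amplitude law is a point mass and has no density")

#' @export
amp_density.amp_exponential <- function(dist, a) {
  d <- stats::dexp(dist$sign * a, rate = 1 / dist$scale)
  d[dist$sign * a < 0] <- 0
  d
}

#' @export
amp_density.amp_uniform <- function(dist, a)
  stats::dunif(a, dist$l1, dist$l2)

#' @export
amp_density.amp_tgauss <- function(dist, a) {
  d <- stats::dnorm(a, dist$a_p, dist$sigma_g) /
    pnorm(0, dist$a_p, dist$sigma_g)
  d[a > 0] <- 0
  d
}

# A~(s) = E[e^{s a}]; s may be complex for the closed-form families.
amp_mgf <- function(dist, s) UseMethod("amp_mgf")

#' @export
amp_mgf.amp_delta <- function(dist, s) exp(s * dist$a)

#' @export
amp_mgf.amp_exponential <- function(dist, s) {
  a <- dist$sign * dist$scale
  if (dist$sign > 0 && any(Re(s * a) >= 1))
    stop("excitatory exponential kernel has a pole at s = 1/a_e")
  1 / (1 - s * a)
}

#' @export
amp_mgf.amp_uniform <- function(dist, s) {
  l1 <- dist$l1; l2 <- dist$l2
  (exp(s * l2) - exp(s * l1)) / (s * (l2 - l1))
}

#' @export
amp_mgf.amp_tgauss <- function(dist, s) {
  if (is.complex(s)) stop("truncated-Gaussian kernel supports real s only")
  mu <- dist$a_p; sg <- dist$sigma_g
  # log Phi evaluated stably far in the tail
  lnum <- pnorm(-(mu + s * sg^2) / sg, log.p = TRUE)
  lden <- pnorm(-mu / sg, log.p = TRUE)
  exp(s * mu + s^2 * sg^2 / 2 + lnum - lden)
}

#' Laplace kernel of the synaptic flux
#'
#' Computes \eqn{Q(s) = R\,(\tilde A(s) - 1)/s}, the factor relating the
#' bilateral Laplace transform of the synaptic probability flux to that of
#' the membrane-potential density, \eqn{\tilde J(s) = \tilde P(s) Q(s)}.
#' As \eqn{s \to 0}, \eqn{Q(s)/R \to \langle a \rangle}; a second-order
#' Taylor expansion is substituted below `|s * mean| < 1e-6` to avoid 0/0.
#'
#' Closed forms: delta \eqn{-R(1-e^{s a})/s}; inhibitory exponential
#' \eqn{R a/(1-s a)}; uniform
#' \eqn{R[(e^{l_2 s}-e^{l_1 s})/(s(l_2-l_1)) - 1]/s}; truncated Gaussian via
#' its transform \eqn{e^{s a_p + s^2\sigma_G^2/2}\,\Phi(-(a_p+s\sigma_G^2)/\sigma_G)/\Phi(-a_p/\sigma_G)}.
#' The excitatory exponential has a pole at \eqn{s = 1/a_e} and errors there.
#'
#' @param dist an [amp_dist][amp_delta] object.
#' @param s Laplace variable (1/mV); real vector, or complex for all laws
#'   except the truncated Gaussian.
#' @param rate Poisson arrival rate in kicks/ms.
#' @return values of `Q(s)`, same length as `s`.
#' @examples
#' amp_kernel_Q(amp_delta(-1), 1, rate = 0.1)    # -0.0632
#' amp_kernel_Q(amp_delta(-1), 1e-9, rate = 0.1) # -> rate * mean = -0.1
#' @export
amp_kernel_Q <- function(dist, s, rate) {
  m <- amp_moments(dist)
  scale <- abs(m$mean) + sqrt(m$var)
  small <- Mod(s) * max(scale, 1e-12) < 1e-4
  out <- if (is.complex(s)) complex(length(s)) else numeric(length(s))
  if (any(small)) {
    ss <- s[small]
    out[small] <- rate * (m$mean + ss * m$m2 / 2 + ss^2 * m$m3 / 6)
  }
  if (any(!small)) {
    ss <- s[!small]
    out[!small] <- rate * (amp_mgf(dist, ss) - 1) / ss
  }
  out
}

# Integral of the kernel: int_0^s Q(u) du in closed form where available
# (delta, exponential, uniform); NULL means "integrate numerically" (tgauss).
amp_kernel_int <- function(dist, s, rate) UseMethod("amp_kernel_int")

#' @export
amp_kernel_int.amp_delta <- function(dist, s, rate)
  -rate * ein(-dist$a * s)

#' @export
amp_kernel_int.amp_exponential <- function(dist, s, rate) {
  a <- dist$sign * dist$scale
  -rate * log(1 - s * a)
}

#' @export
amp_kernel_int.amp_uniform <- function(dist, s, rate) {
  g <- function(l, s) {
    # int_0^s (e^{lu} - 1 - lu)/u^2 du, stable for small |l s|
    x <- l * s
    small <- Mod(x) < 1e-5
    out <- if (is.complex(s)) complex(length(s)) else numeric(length(s))
    if (any(small)) {
      xs <- x[small]
      out[small] <- l * (xs / 2 + xs^2 / 12 + xs^3 / 72) # series head
    }
    if (any(!small)) {
      ss <- s[!small]; xx <- x[!small]
      out[!small] <- -(exp(xx) - 1 - xx) / ss - l * ein(-xx)
    }
    out
  }
  -rate / (dist$l2 - dist$l1) * (g(dist$l1, s) - g(dist$l2, s))
}

#' @export
amp_kernel_int.amp_tgauss <- function(dist, s, rate) NULL

#' Parse an amplitude-distribution spec string
#'
#' Accepts the compact strings used in configuration files and on the command
#' line: `"delta:a_i=-1"`, `"exp:a=-1"`, `"uniform:l1=-2,l2=0"`,
#' `"tgauss:ap=-0.7766,sg=0.7766"`.
#'
#' @param spec character scalar.
#' @return an [amp_dist][amp_delta] object.
#' @export
parse_amp_dist <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed distribution spec: ", spec)
  kind <- parts[1]
  kv <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
    vapply(kv, `[`, character(1), 1))
  switch(kind,
    delta   = amp_delta(vals[["a_i"]]),
    exp     = amp_exponential(vals[["a"]]),
    uniform = amp_uniform(vals[["l1"]], vals[["l2"]]),
    tgauss  = amp_tgauss(vals[["ap"]], vals[["sg"]]),
    stop("unknown distribution family: ", kind))
}

# Compact spec string for an amp_dist (inverse of parse_amp_dist).
amp_spec_string <- function(dist) {
  if (inherits(dist, "amp_delta")) sprintf("delta:a_i=%g", dist$a)
  else if (inherits(dist, "amp_exponential"))
    sprintf("exp:a=%g", dist$sign * dist$scale)
  else if (inherits(dist, "amp_uniform"))
    sprintf("uniform:l1=%g,l2=%g", dist$l1, dist$l2)
  else sprintf("tgauss:ap=%g,sg=%g", dist$a_p, dist$sigma_g)
}

#' Calibrate a truncated Gaussian with equal peak and width
#'
#' Finds the common magnitude \eqn{c > 0} such that the Gaussian with peak
#' \eqn{a_p = -c} and width \eqn{\sigma_G = c}, truncated to
#' \eqn{(-\infty, 0]}, has mean amplitude `target_mean` (default -1 mV).
#'
#' @param target_mean desired mean amplitude (mV, negative).
#' @return the calibrated magnitude `c` (mV).
#' @examples
#' tgauss_calibrate(-1)  # ~0.7766
#' @export
tgauss_calibrate <- function(target_mean = -1) {
  stopifnot(target_mean < 0)
  f <- function(cc) amp_moments(amp_tgauss(-cc, cc))$mean - target_mean
  scale <- abs(target_mean)
  stats::uniroot(f, c(0.1 * scale, 3 * scale), tol = 1e-12)$root
}
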