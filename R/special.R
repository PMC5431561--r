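# Special functions used by the Laplace engine.  Real arguments are served by
# pracma where possible; complex exponential integrals (needed on the rotated
# integration contour) have no in-environment provider and are implemented here.

#' Complementary exponential integral Ein
#'
#' `ein(z)` computes \eqn{Ein(z) = \int_0^z (1-e^{-t})/t \, dt}, the entire
#' complementary exponential integral, for real or complex `z` with
#' \eqn{Re(z) \ge 0}.  It satisfies
#' \eqn{Ein(z) = \gamma + \log z + E_1(z)}, and is the building block of the
#' closed-form voltage generating functions for delta and uniform synaptic
#' amplitude distributions.
#'
#' A power series is used for \eqn{|z| \le 12}; beyond that the identity with
#' \eqn{E_1} is used, with \eqn{E_1} evaluated by a modified Lentz continued
#' fraction (valid for \eqn{|\arg z| < \pi}).
#'
#' @param z numeric or complex vector, `Re(z) >= 0`.
#' @return vector of the same mode as `z` (complex in, complex out).
#' @examples
#' ein(1)                     # 0.7965996
#' ein(1e-8) / 1e-8           # -> 1 (Ein(z) ~ z for small z)
#' @export
ein <- function(z) {
  cplx <- is.complex(z)
  zz <- as.complex(z)
  out <- complex(length(zz))
  sm <- Mod(zz) <= 12
  if (any(sm)) {
    zs <- zz[sm]
    acc <- zs * 0
    p <- rep(1 + 0i, length(zs))
    for (n in 1:60) {
      p <- p * zs / n
      acc <- acc + (-1)^(n + 1) * p / n
    }
    out[sm] <- acc
  }
  if (any(!sm)) {
    zl <- zz[!sm]
    out[!sm] <- 0.57721566490153286 + log(zl) + e1_cf(zl)
  }
  if (cplx) out else Re(out)
}

# E1(z) by modified Lentz continued fraction; |z| > ~2, |arg z| < pi.
e1_cf <- function(z) {
  vapply(z, function(w) {
    b <- w + 1
    cc <- 1 / 1e-300
    d <- 1 / b
    h <- d
    for (i in 1:300) {
      an <- -i * i
      b <- b + 2
      d <- 1 / (an * d + b)
      cc <- b + an / cc
      del <- cc * d
      h <- h * del
      if (Mod(del - 1) < 1e-15) break
    }
    exp(-w) * h
  }, complex(1))
}

# Scaled complementary error function erfcx(x) = exp(x^2) erfc(x) for real x.
# pracma::erfcx returns NaN beyond ~x = 27; guard with the asymptotic series.
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  if (any(big)) {
    xb <- x[big]
    out[big] <- (1 - 0.5 / xb^2 + 0.75 / xb^4 - 1.875 / xb^6) / (xb * sqrt(pi))
  }
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  out
}

# Gauss-Legendre nodes/weights on [0,1], cached by order.
gl01 <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      g <- pracma::gaussLegendre(n, 0, 1)
      cache[[key]] <<- list(x = g$x, w = g$w)
    }
    cache[[key]]
  }
})
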