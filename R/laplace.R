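# The Laplace-space engine.
#
# For a configuration (neuron, drive, inhibition) this builds the function
# bundle on which every exact statistic rests:
#
#   log Z0(s)  log of the generating function of the free (no-threshold)
#              stationary voltage: log H_e + mu0 s + tau * int_0^s Q_i(u) du
#   dlogZ0(s)  its derivative, tau (mu0/tau + Q_e + Q_i) in closed form
#   F(s)       e^{s v_th} D_e(s) - e^{s v_re}, with D_e = 1/(1 - s a_e) for
#              exponentially distributed excitatory kicks and 1 for DC drive
#   A(s)       e^{s v_re} / Z0,   B(s) = F(s) / Z0
#   xbar       upper integration limit where 1/Z0 vanishes: 1/a_e for
#              excitatory kicks, +Inf for DC
#
# The stationary rate is 1/(tau r0) = int_0^xbar F(c)/(c Z0(c)) dc, and the
# first-passage moments and spectra follow from oscillatory integrals of
# d/ds A and d/ds B against s^{i omega tau}.
#
# All work is done on log Z0 (never Z0) so that the e^{mu0 s} growth cannot
# overflow; A and B are assembled as exp(s v - log Z0).

#' Build the Laplace-space function bundle
#'
#' Assembles `log Z0`, its derivative, `F`, `A`, `B` and the integration
#' limit for a neuron/drive/inhibition configuration.  Closed forms are used
#' for the delta, exponential and uniform amplitude laws; the truncated
#' Gaussian integrates its kernel numerically on an adaptively grown grid
#' cached in a spline.
#'
#' Validity flags: `"ok"`; `"silent_dc"` when a DC-only drive has
#' \eqn{\mu_0 \le v_{th}} (the neuron can never fire, the rate integral
#' diverges and the rate is 0); `"unsupported_supra_dc_with_shot"` when
#' excitatory kicks are combined with a supra-threshold DC (no integration
#' limit exists and the analytic method fails; use the simulator there).
#'
#' @param neuron a [lif_neuron()].
#' @param drive a [drive_dc()] or [drive_shot()].
#' @param inh an [inh_input()] or `NULL`.
#' @return object of class `laplace_bundle`.
#' @examples
#' lb <- laplace_bundle(lif_neuron(), drive_dc(11), inh_input(amp_delta(-1), 100))
#' lb$logZ0(0)                      # 0: Z0(0) = 1
#' @export
laplace_bundle <- function(neuron, drive, inh = NULL) {
  tau <- neuron$tau; v_th <- neuron$v_th; v_re <- neuron$v_re
  eff <- effective_input(drive, inh, neuron)
  mu0 <- drive$mu0

  has_shot <- drive$kind == "shot" && drive$R_e > 0
  validity <- "ok"
  if (has_shot && mu0 > v_th) validity <- "unsupported_supra_dc_with_shot"
  if (!has_shot && mu0 <= v_th) validity <- "silent_dc"

  Re_ms <- if (has_shot) drive$R_e / 1000 else 0
  a_e <- if (has_shot) drive$a_e else 0
  Ri_ms <- if (is.null(inh)) 0 else inh$R_i / 1000
  dist <- if (is.null(inh)) NULL else inh$dist
  xbar <- if (has_shot) 1 / a_e else Inf

  has_inh <- Ri_ms > 0
  closed <- !has_inh || !is.null(amp_kernel_int(dist, 0.1, Ri_ms))

  # inhibitory part of log Z0: tau * int_0^s Q_i
  if (!has_inh) {
    inh_int <- function(s) s * 0
  } else if (closed) {
    inh_int <- function(s) tau * amp_kernel_int(dist, s, Ri_ms)
  } else {
    inh_int <- tgd_cumulative(dist, Ri_ms, tau, mu0, v_th, has_shot, xbar)
  }

  logHe <- if (has_shot) {
    function(s) -tau * Re_ms * log(1 - s * a_e)
  } else function(s) s * 0

  logZ0_noHe <- function(s) mu0 * s + inh_int(s)
  logZ0 <- function(s) logZ0_noHe(s) + logHe(s)

  dlogZ0 <- function(s) {
    out <- mu0 + 0 * s
    if (has_shot) out <- out + tau * Re_ms * a_e / (1 - s * a_e)
    if (has_inh) out <- out + tau * amp_kernel_Q(dist, s, Ri_ms)
    out
  }

  De <- if (has_shot) function(s) 1 / (1 - s * a_e) else function(s) 1 + 0 * s

  structure(list(
    neuron = neuron, drive = drive, inh = inh,
    mu_T = eff$mu_T, sigma2 = eff$sigma2,
    tau = tau, v_th = v_th, v_re = v_re, mu0 = mu0,
    Re_ms = Re_ms, a_e = a_e, Ri_ms = Ri_ms, dist = dist,
    xbar = xbar, validity = validity, closed_form = closed,
    logZ0 = logZ0, logZ0_noHe = logZ0_noHe, dlogZ0 = dlogZ0, De = De
  ), class = "laplace_bundle")
}

#' @export
print.laplace_bundle <- function(x, ...) {
  cat("Laplace bundle\n")
  cat(sprintf("  mu_T = %g mV, sigma2 = %g mV^2, xbar = %g, validity = %s\n",
              x$mu_T, x$sigma2, x$xbar, x$validity))
  invisible(x)
}

# Cumulative kernel integral for the truncated Gaussian: grows a panel grid
# until the rate integrand is negligible (DC) or xbar is reached (shot), and
# returns a spline of tau * int_0^s Q_i.
tgd_cumulative <- function(dist, Ri_ms, tau, mu0, v_th, has_shot, xbar) {
  gl <- gl01(15)
  smax_cap <- if (has_shot) xbar * (1 - 1e-10) else 5000
  edges <- 0; acc <- 0
  s <- 0; h <- 0.02
  vals <- 0
  repeat {
    h <- min(h * 1.25, 0.5)
    s2 <- min(s + h, smax_cap)
    nodes <- s + (s2 - s) * gl$x
    acc <- acc + (s2 - s) * sum(gl$w * amp_kernel_Q(dist, nodes, Ri_ms))
    s <- s2
    edges <- c(edges, s); vals <- c(vals, acc)
    if (s >= smax_cap) break
    if (!has_shot && s > 1) {
      expo <- s * v_th - (mu0 * s + tau * acc)
      if (expo < -45 && s > 5) break
      if (expo > 200) break  # divergent (silent) configuration: stop growing
    }
    if (length(edges) > 4000) break
  }
  sp <- stats::splinefun(edges, tau * vals, method = "fmm")
  smax <- s
  function(s) {
    if (is.complex(s))
      stop("truncated-Gaussian log Z0 is available for real s only")
    out <- sp(pmin(s, smax))
    over <- s > smax
    if (any(over))  # extend with the tail form Q ~ -R/s
      out[over] <- sp(smax) - tau * Ri_ms * log(s[over] / smax)
    out
  }
}

# Rate integrand F(c)/(c Z0(c)), numerically stable across the whole range.
# `one_minus` optionally supplies an exact value of (1 - c a_e) near xbar.
rate_integrand <- function(lb, cc, one_minus = NULL) {
  v_th <- lb$v_th; v_re <- lb$v_re
  out <- numeric(length(cc))
  small <- cc < 1e-6
  if (any(small)) {
    a_e <- lb$a_e
    f1 <- v_th + a_e - v_re
    f2 <- v_th^2 / 2 + a_e * v_th + a_e^2 - v_re^2 / 2
    out[small] <- f1 + cc[small] * (f2 - f1 * lb$mu_T)
  }
  if (any(!small)) {
    cs <- cc[!small]
    if (lb$Re_ms > 0) {
      # near xbar, (1 - c a_e) loses precision; use the exact value when the
      # caller's substitution supplies it
      om <- if (is.null(one_minus)) 1 - cs * lb$a_e else one_minus[!small]
      lz <- lb$logZ0_noHe(cs) - lb$tau * lb$Re_ms * log(om)
      lde <- -log(om)
    } else {
      lz <- lb$logZ0(cs)
      lde <- 0
    }
    out[!small] <- (exp(cs * v_th - lz + lde) - exp(cs * v_re - lz)) / cs
  }
  out
}
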