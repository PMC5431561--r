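# Neuron constants, drive specification and the effective-input / noise
# parameterization on which all input configurations are compared.
#
# Units: millivolts and milliseconds internally; rates are Hz at every
# user-facing interface and kicks/ms inside the engine.

#' Leaky integrate-and-fire neuron constants
#'
#' @param tau membrane time constant (ms).
#' @param v_th firing threshold (mV).
#' @param v_re reset potential (mV).
#' @return object of class `lif_neuron`.
#' @examples
#' lif_neuron()  # tau = 20 ms, v_th = 10 mV, v_re = 5 mV
#' @export
lif_neuron <- function(tau = 20, v_th = 10, v_re = 5) {
  stopifnot(tau > 0)
  if (v_th <= v_re) stop("v_th must exceed v_re")
  structure(list(tau = tau, v_th = v_th, v_re = v_re), class = "lif_neuron")
}

#' @export
print.lif_neuron <- function(x, ...) {
  cat(sprintf("LIF neuron: tau = %g ms, v_th = %g mV, v_re = %g mV\n",
              x$tau, x$v_th, x$v_re))
  invisible(x)
}

#' Excitatory drive specification
#'
#' `drive_dc()` is a constant current; `drive_shot()` adds a Poisson train of
#' exponentially distributed excitatory kicks (mean `a_e` mV, rate `R_e` Hz)
#' on top of a DC term `mu0`.  The analytic engine requires `mu0 < v_th` when
#' excitatory kicks are present (with a supra-threshold DC plus excitatory
#' shot noise no integration limit \eqn{\bar x} exists and the Laplace method
#' fails; the simulator still handles that regime).
#'
#' @param mu0 DC current (mV).
#' @param a_e mean EPSP amplitude (mV), `> 0`.
#' @param R_e excitatory Poisson rate (Hz), `>= 0`.
#' @return object of class `lif_drive`.
#' @export
drive_dc <- function(mu0) {
  stopifnot(is.finite(mu0))
  structure(list(kind = "dc", mu0 = mu0), class = "lif_drive")
}

#' @rdname drive_dc
#' @export
drive_shot <- function(mu0 = 0, a_e, R_e) {
  stopifnot(a_e > 0, R_e >= 0)
  structure(list(kind = "shot", mu0 = mu0, a_e = a_e, R_e = R_e),
            class = "lif_drive")
}

#' @export
print.lif_drive <- function(x, ...) {
  if (x$kind == "dc") cat(sprintf("DC drive: mu0 = %g mV\n", x$mu0))
  else cat(sprintf(
    "Excitatory shot drive: mu0 = %g mV, a_e = %g mV, R_e = %g Hz\n",
    x$mu0, x$a_e, x$R_e))
  invisible(x)
}

#' Inhibitory Poisson input
#'
#' @param dist an inhibitory [amp_dist][amp_delta] (mean `< 0` unless
#'   `R_i = 0`).
#' @param R_i inhibitory Poisson rate (Hz), `>= 0`.
#' @return object of class `inh_input`.
#' @export
inh_input <- function(dist, R_i) {
  stopifnot(inherits(dist, "amp_dist"), R_i >= 0)
  if (R_i > 0 && amp_moments(dist)$mean >= 0)
    stop("inhibitory amplitude distribution must have negative mean")
  structure(list(dist = dist, R_i = R_i), class = "inh_input")
}

#' @export
print.inh_input <- function(x, ...) {
  cat(sprintf("Inhibitory input: R_i = %g Hz, %s\n", x$R_i, format(x$dist)))
  invisible(x)
}

#' Effective mean input and total noise intensity
#'
#' For Poisson streams with i.i.d. amplitudes the effective mean input is
#' \eqn{\mu_T = \mu_e + \tau R_i \langle a_i \rangle} (with
#' \eqn{\mu_e = \mu_0} or \eqn{\mu_0 + \tau R_e \langle a_e \rangle}) and the
#' total noise intensity is
#' \eqn{\sigma^2 = \sum_x R_x \tau (\langle a_x\rangle^2 + var[a_x])},
#' summing the variance contributed by Poisson timing and by amplitude
#' variability of each stream.
#'
#' @param drive a [drive_dc()] or [drive_shot()] object.
#' @param inh an [inh_input()] object (or `NULL` for none).
#' @param neuron a [lif_neuron()].
#' @return list with `mu_T`, `sigma2` (mV, mV^2), and the components `mu_e`,
#'   `mu_i`.
#' @examples
#' effective_input(drive_dc(11), inh_input(amp_delta(-1), 100), lif_neuron())
#' @export
effective_input <- function(drive, inh = NULL, neuron = lif_neuron()) {
  tau <- neuron$tau
  mu_e <- drive$mu0
  sig2 <- 0
  if (drive$kind == "shot") {
    Re_ms <- drive$R_e / 1000
    mu_e <- mu_e + tau * Re_ms * drive$a_e
    sig2 <- sig2 + Re_ms * tau * 2 * drive$a_e^2  # mean^2 + var, exponential
  }
  mu_i <- 0
  if (!is.null(inh) && inh$R_i > 0) {
    m <- amp_moments(inh$dist)
    Ri_ms <- inh$R_i / 1000
    mu_i <- tau * Ri_ms * m$mean
    sig2 <- sig2 + Ri_ms * tau * m$m2
  }
  list(mu_T = mu_e + mu_i, sigma2 = sig2, mu_e = mu_e, mu_i = mu_i)
}

#' Solve drive parameters for a target effective input and noise intensity
#'
#' Inverts [effective_input()]: given a target \eqn{(\mu_T, \sigma^2)} and an
#' inhibitory amplitude law, returns the inhibitory rate and the excitatory
#' drive that realize it.  For `kind = "dc"` the solution is unique:
#' \eqn{R_i = \sigma^2 / (\tau \langle a_i^2 \rangle)} and
#' \eqn{\mu_0 = \mu_T - \tau R_i \langle a_i \rangle}; configurations with
#' \eqn{\mu_0 \le v_{th}} are flagged `silent` (the neuron can then never
#' fire under purely inhibitory kicks) but still returned.  For
#' `kind = "shot"` the balanced convention is used: \eqn{R_e = R_i} with
#' \eqn{\langle a_e \rangle = |\langle a_i \rangle|}, and `mu0` fixed at
#' `mu_T` so the two Poisson streams cancel in the mean.
#'
#' @param mu_T target effective input (mV).
#' @param sigma2 target noise intensity (mV^2), `>= 0`.
#' @param dist inhibitory [amp_dist][amp_delta].
#' @param neuron a [lif_neuron()].
#' @param kind `"dc"` or `"shot"`.
#' @return list with `drive`, `inh`, and logical `silent`.
#' @examples
#' solve_drive(9, 2, amp_delta(-1))      # R_i = 100 Hz, mu0 = 11 mV
#' solve_drive(9, 2, amp_delta(-0.1))    # R_i = 10 kHz, mu0 = 29 mV
#' @export
solve_drive <- function(mu_T, sigma2, dist, neuron = lif_neuron(),
                        kind = c("dc", "shot")) {
  kind <- match.arg(kind)
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  tau <- neuron$tau
  m <- amp_moments(dist)
  if (sigma2 == 0) {
    return(list(drive = drive_dc(mu_T), inh = inh_input(dist, 0),
                silent = mu_T <= neuron$v_th))
  }
  if (m$m2 <= 0) stop("amplitude law carries no noise; unreachable sigma2")
  if (kind == "dc") {
    Ri_ms <- sigma2 / (tau * m$m2)
    mu0 <- mu_T - tau * Ri_ms * m$mean
    list(drive = drive_dc(mu0), inh = inh_input(dist, 1000 * Ri_ms),
         silent = mu0 <= neuron$v_th)
  } else {
    a_e <- abs(m$mean)
    if (a_e == 0) stop("balanced shot drive needs a non-zero mean amplitude")
    R_ms <- sigma2 / (tau * (2 * a_e^2 + m$m2))
    list(drive = drive_shot(mu0 = mu_T, a_e = a_e, R_e = 1000 * R_ms),
         inh = inh_input(dist, 1000 * R_ms),
         silent = FALSE)
  }
}

#' Tonic firing rate of the noiseless neuron
#'
#' For a constant supra-threshold input the interspike interval is the
#' deterministic relaxation time from reset to threshold:
#' \eqn{1/r_0^t = \tau \log[(\mu_T - v_{re})/(\mu_T - v_{th})]}.  Returns 0
#' for \eqn{\mu_T \le v_{th}}.
#'
#' @param mu_T effective input (mV); vectorized.
#' @param neuron a [lif_neuron()].
#' @return firing rate (Hz).
#' @examples
#' tonic_rate(12)  # ~39.92 Hz
#' tonic_rate(9)   # 0
#' @export
tonic_rate <- function(mu_T, neuron = lif_neuron()) {
  out <- numeric(length(mu_T))
  sup <- mu_T > neuron$v_th
  out[sup] <- 1000 / (neuron$tau *
    log((mu_T[sup] - neuron$v_re) / (mu_T[sup] - neuron$v_th)))
  out
}
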