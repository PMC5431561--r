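# The user-facing model object: a LIF neuron under a fully specified
# shot-noise input configuration, with the Laplace bundle attached.

#' LIF neuron driven by inhibitory shot noise
#'
#' Constructs the model object on which all exact statistics, simulations
#' and plots operate.  The input configuration can be given either directly
#' (`drive` + `R_i`) or through the effective parameterization
#' (`mu_T`, `sigma2`), in which case [solve_drive()] inverts the
#' effective-input relations: for DC drive the unique
#' \eqn{(R_i, \mu_0)}; for balanced excitatory shot drive
#' (`drive_kind = "shot"`) the convention \eqn{R_e = R_i},
#' \eqn{\langle a_e\rangle = |\langle a_i\rangle|}, \eqn{\mu_0 = \mu_T}.
#'
#' @param dist inhibitory amplitude law ([amp_delta()] and friends).
#' @param mu_T,sigma2 target effective input (mV) and noise intensity
#'   (mV^2); alternative to `drive`/`R_i`.
#' @param drive explicit [drive_dc()]/[drive_shot()] object.
#' @param R_i explicit inhibitory rate (Hz), used with `drive`.
#' @param neuron a [lif_neuron()].
#' @param drive_kind `"dc"` or `"shot"`, used with `mu_T`/`sigma2`.
#' @return object of class `shot_lif` with components `neuron`, `drive`,
#'   `inh`, `mu_T`, `sigma2`, `silent`, and the Laplace bundle `lf`.
#' @examples
#' m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)
#' summary(m)
#' @export
shot_lif <- function(dist, mu_T = NULL, sigma2 = NULL, drive = NULL,
                     R_i = NULL, neuron = lif_neuron(),
                     drive_kind = c("dc", "shot")) {
  drive_kind <- match.arg(drive_kind)
  stopifnot(inherits(dist, "amp_dist"))
  if (!is.null(mu_T)) {
    if (is.null(sigma2)) stop("sigma2 must accompany mu_T")
    sol <- solve_drive(mu_T, sigma2, dist, neuron, drive_kind)
    drive <- sol$drive; inh <- sol$inh; silent <- sol$silent
  } else {
    if (is.null(drive) || is.null(R_i))
      stop("give either (mu_T, sigma2) or (drive, R_i)")
    inh <- inh_input(dist, R_i)
    silent <- drive$kind == "dc" && drive$mu0 <= neuron$v_th
  }
  lf <- laplace_bundle(neuron, drive, inh)
  structure(list(neuron = neuron, drive = drive, inh = inh,
                 mu_T = lf$mu_T, sigma2 = lf$sigma2,
                 silent = silent, lf = lf),
            class = "shot_lif")
}

#' @export
print.shot_lif <- function(x, ...) {
  cat("LIF neuron with shot-noise input\n")
  print(x$neuron)
  print(x$drive)
  print(x$inh)
  cat(sprintf("  effective input mu_T = %g mV, noise sigma2 = %g mV^2\n",
              x$mu_T, x$sigma2))
  if (x$silent) cat("  silent: mu_0 <= v_th with purely inhibitory kicks\n")
  if (x$lf$validity == "unsupported_supra_dc_with_shot")
    cat("  analytic statistics unavailable (supra-threshold DC + kicks)\n")
  invisible(x)
}

#' @export
summary.shot_lif <- function(object, ...) {
  fs <- firing_stats(object)
  out <- list(model = object, stats = fs)
  class(out) <- "summary.shot_lif"
  out
}

#' @export
print.summary.shot_lif <- function(x, ...) {
  print(x$model)
  cat("\nExact firing statistics:\n  ")
  print(x$stats)
  invisible(x)
}

#' @export
coef.shot_lif <- function(object, ...) {
  d <- object$drive
  c(mu_T = object$mu_T, sigma2 = object$sigma2, mu0 = d$mu0,
    R_i = object$inh$R_i,
    R_e = if (d$kind == "shot") d$R_e else 0,
    a_e = if (d$kind == "shot") d$a_e else NA_real_)
}

#' Simulate spike trains from a shot-noise LIF model
#'
#' Event-driven, exact simulation of the model (see [simulate_neuron()]).
#' `nsim` is the number of spikes returned after burn-in.
#'
#' @param object a [shot_lif()] model.
#' @param nsim number of spikes to collect.
#' @param seed optional seed passed to [set.seed()].
#' @param burn_in_spikes spikes discarded before collection.
#' @param ... unused.
#' @return a `spike_train` (numeric spike times in ms).
#' @export
simulate.shot_lif <- function(object, nsim = 10000, seed = NULL,
                              burn_in_spikes = NULL, ...) {
  simulate_neuron(object, n_spikes = nsim, seed = seed,
                  burn_in_spikes = burn_in_spikes)
}

#' Plot method for shot-noise LIF models
#'
#' Draws the ISI density (continuous part, with the deterministic atom
#' marked when present) and the normalized spike-train spectrum.
#'
#' @param x a [shot_lif()] model.
#' @param which `"isi"`, `"spectrum"` or `"both"`.
#' @param f_max largest frequency (Hz) for the spectrum panel.
#' @param ... unused.
#' @export
plot.shot_lif <- function(x, which = c("both", "isi", "spectrum"),
                          f_max = 100, ...) {
  which <- match.arg(which)
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "isi")) {
    d <- isi_density(x)
    keep <- d$t_ms < 6 * firing_stats(x)$mean_isi
    graphics::plot(d$t_ms[keep], d$q[keep], type = "l",
                   xlab = "ISI (ms)", ylab = "q(t) (1/ms)",
                   main = "ISI density")
    if (isTRUE(attr(d, "atom_mass") > 1e-6))
      graphics::abline(v = attr(d, "atom_time_ms"), lty = 3)
  }
  if (which %in% c("both", "spectrum")) {
    f <- seq(0.5, f_max, by = 0.5)
    sp <- spike_spectrum(x, f)
    graphics::plot(sp$f_hz, sp$C_hat / attr(sp, "r0_hz"), type = "l",
                   xlab = "f (Hz)", ylab = expression(hat(C) / r[0]),
                   main = "Spike-train spectrum")
  }
  invisible(x)
}
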