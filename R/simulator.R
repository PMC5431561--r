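# R-side interface to the exact event-driven simulator.

amp_code <- function(dist) {
  if (inherits(dist, "amp_delta")) list(code = 0L, p1 = dist$a, p2 = 0)
  else if (inherits(dist, "amp_exponential"))
    list(code = 1L, p1 = dist$sign * dist$scale, p2 = 0)
  else if (inherits(dist, "amp_uniform"))
    list(code = 2L, p1 = dist$l1, p2 = dist$l2)
  else list(code = 3L, p1 = dist$a_p, p2 = dist$sigma_g)
}

#' Exact event-driven simulation of a shot-noise LIF neuron
#'
#' Simulates the membrane equation exactly: between Poisson events the
#' membrane relaxes in closed form, deterministic threshold crossings are
#' resolved analytically, and kicks are applied instantaneously (excitatory
#' overshoot of the threshold fires at the kick instant).  Excitatory and
#' inhibitory streams are merged into a single exponential clock with the
#' event type drawn Bernoulli(\eqn{R_e/(R_e+R_i)}), which has the same law
#' as two independent Poisson clocks with fewer random draws.
#'
#' The default burn-in discards the first
#' \eqn{\max(100, \lceil 10\tau r_0^{guess}\rceil)} spikes so the voltage
#' ensemble reaches stationarity before statistics are collected.
#'
#' @param object a [shot_lif()] model, or anything accepted by [shot_lif()].
#' @param n_spikes number of spikes to return (after burn-in).
#' @param seed optional integer passed to [set.seed()].
#' @param burn_in_spikes override the burn-in spike count.
#' @param max_events event budget before declaring the neuron silent.
#' @return object of class `spike_train`: numeric vector of spike times
#'   (ms, increasing), with attributes `duration` and `seed`.
#' @examples
#' m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)
#' st <- simulate_neuron(m, n_spikes = 1000, seed = 1)
#' isi_stats(st)$r0      # ~9 Hz
#' @export
simulate_neuron <- function(object, n_spikes = 10000, seed = NULL,
                            burn_in_spikes = NULL, max_events = 5e8) {
  m <- object
  if (!inherits(m, "shot_lif")) stop("need a shot_lif model")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burn_in_spikes)) burn_in_spikes <- 200L
  d <- m$drive
  ic <- amp_code(m$inh$dist)
  ts <- cpp_simulate_lif(
    m$neuron$tau, m$neuron$v_th, m$neuron$v_re, d$mu0,
    if (d$kind == "shot") d$R_e / 1000 else 0,
    if (d$kind == "shot") d$a_e else 0,
    m$inh$R_i / 1000, ic$code, ic$p1, ic$p2,
    as.integer(n_spikes), as.integer(burn_in_spikes), max_events)
  structure(ts, duration = if (length(ts)) max(ts) else 0,
            seed = seed, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d spikes over %.1f s\n",
              length(x), attr(x, "duration") / 1000))
  invisible(x)
}

#' Rate and CV estimates from a spike train
#'
#' \eqn{r_0 = (n-1)/(t_n - t_1)}; the CV is the sample coefficient of
#' variation of the interspike intervals.  Standard errors use the
#' asymptotic formulas: \eqn{SE[r_0] = r_0\, CV/\sqrt{n}} and
#' \eqn{SE[CV] = CV\sqrt{(1 + CV^2 \,(\kappa - 1)/4) / n}} with
#' \eqn{\kappa} replaced by the normal-theory simplification
#' \eqn{SE[CV] \approx CV \sqrt{1/(2n) + CV^2/n}}, adequate at the sample
#' sizes used here.
#'
#' @param train a `spike_train` or numeric vector of spike times (ms).
#' @return list with `r0` (Hz), `cv`, `se_r0`, `se_cv`, `n` (number of
#'   intervals).
#' @export
isi_stats <- function(train) {
  t <- as.numeric(train)
  if (length(t) < 2) stop("need at least 2 spikes")
  isi <- diff(t)
  n <- length(isi)
  m <- mean(isi)
  s <- stats::sd(isi)
  cv <- s / m
  r0 <- 1000 / m
  list(r0 = r0, cv = cv,
       se_r0 = r0 * cv / sqrt(n),
       se_cv = cv * sqrt(1 / (2 * n) + cv^2 / n),
       n = n)
}

#' Empirical spike-train spectrum from binned counts
#'
#' Bins each realization at `bin_ms`, removes the mean, and averages the
#' squared modulus of the discrete Fourier transform over realizations,
#' normalized by the trace duration so the high-frequency plateau estimates
#' the rate in 1/s -- directly comparable with [spike_spectrum()].
#'
#' @param model a [shot_lif()] model.
#' @param n_realizations number of independent traces.
#' @param duration_s trace length (s).
#' @param bin_ms bin width (ms).
#' @param seed optional seed.
#' @return data frame with `f_hz` and `C_hat` (1/s).
#' @export
spectrum_estimate <- function(model, n_realizations = 20, duration_s = 16,
                              bin_ms = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T_ms <- duration_s * 1000
  nb <- floor(T_ms / bin_ms)
  acc <- NULL
  r0g <- firing_rate(model)
  n_need <- ceiling(r0g * duration_s * 1.25) + 50
  for (r in seq_len(n_realizations)) {
    st <- simulate_neuron(model, n_spikes = n_need)
    while (max(st) < T_ms) {   # rare: rate fluctuated low, extend the draw
      n_need <- ceiling(n_need * 1.3)
      st <- simulate_neuron(model, n_spikes = n_need)
    }
    st <- st[st <= T_ms]
    counts <- tabulate(pmin(floor(st / bin_ms) + 1, nb), nbins = nb)
    X <- stats::fft(counts - mean(counts))
    P <- Mod(X)^2 / duration_s
    acc <- if (is.null(acc)) P else acc + P
  }
  P <- acc / n_realizations
  k <- seq_len(floor(nb / 2))
  data.frame(f_hz = k / duration_s, C_hat = P[k + 1])
}
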