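# Heterogeneous sparse inhibitory networks: direct event-driven simulation
# and the self-consistent mean field.
#
# Each of N neurons has its own excitability mu(j) (uniform on mu_range) and
# exactly K presynaptic partners; the kick delivered by presynaptic neuron k
# has amplitude a_i(k) < 0, drawn once per neuron from the coupling law.
# In the sparse regime the input trains are approximately uncorrelated
# Poisson, so each active neuron sees a Poisson train of rate K * rbar with
# amplitudes from the coupling law - the closure behind the mean field.

#' Sparse inhibitory network configuration
#'
#' @param N number of neurons.
#' @param K in-degree (exactly `K` presynaptic partners each, `K < N`).
#' @param g_dist coupling amplitude law: an inhibitory
#'   [amp_dist][amp_delta] for the per-neuron kick amplitudes
#'   \eqn{a_i(k) = g_i(k)/K < 0}.
#' @param mu_range excitability interval (mV); `mu(j)` i.i.d. uniform on it.
#' @param neuron a [lif_neuron()].
#' @return object of class `network_config`.
#' @examples
#' cfg <- network_config(N = 400, K = 20, g_dist = amp_delta(-0.4))
#' @export
network_config <- function(N = 400, K = 20, g_dist,
                           mu_range = c(10, 11), neuron = lif_neuron()) {
  stopifnot(K >= 1, N >= 2, inherits(g_dist, "amp_dist"))
  if (K >= N) stop("in-degree K must be smaller than N")
  structure(list(N = N, K = K, g_dist = g_dist,
                 mu_range = mu_range, neuron = neuron),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "sparse inhibitory network: N = %d, K = %d, mu in [%g, %g] mV\n",
    x$N, x$K, x$mu_range[1], x$mu_range[2]))
  cat("  coupling:", format(x$g_dist), "\n")
  invisible(x)
}

#' Realize a network: connectivity, weights, excitabilities
#'
#' Draws, for each neuron, exactly `K` distinct presynaptic partners (no
#' self-connections), one kick amplitude per presynaptic neuron from the
#' coupling law, and i.i.d. uniform excitabilities.
#'
#' @param cfg a [network_config()].
#' @param seed optional seed.
#' @return list with `pre` (K x N matrix of presynaptic indices), `a`
#'   (length-N kick amplitude of each neuron as a sender, mV), `mu`
#'   (length-N excitabilities, mV) and `cfg`.
#' @export
build_network <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$N; K <- cfg$K
  pre <- vapply(seq_len(N), function(j)
    sample(setdiff(seq_len(N), j), K), integer(K))
  a <- amp_sample(cfg$g_dist, N)
  mu <- stats::runif(N, cfg$mu_range[1], cfg$mu_range[2])
  list(pre = matrix(pre, nrow = K), a = a, mu = mu, cfg = cfg)
}

#' Event-driven simulation of the sparse inhibitory network
#'
#' Exact event-driven evolution: each spike of neuron `k` instantaneously
#' delivers its kick `a[k]` to all postsynaptic targets.  Silent neurons
#' (no spike in the observation window) are excluded from the rate and CV
#' statistics; the active fraction `n_star` reports their complement.
#'
#' @param net a realized network from [build_network()].
#' @param n_spikes total network spikes to collect after burn-in.
#' @param burn_spikes initial network spikes discarded.
#' @return list with `spikes` (data frame `t`, `id`), per-neuron `rates`
#'   (Hz, `NA` for silent), per-neuron `cv`, `n_star`, `r_bar` (mean rate
#'   over active neurons), `cv_bar`, and the observation window `t_obs`
#'   (ms).
#' @export
simulate_network <- function(net, n_spikes = 2e5, burn_spikes = 2e4) {
  nn <- net$cfg$neuron
  out <- cpp_simulate_network(nn$tau, nn$v_th, nn$v_re, net$mu,
                              net$pre, net$a,
                              as.integer(n_spikes), as.integer(burn_spikes))
  t <- out$t; id <- out$id
  N <- net$cfg$N
  t_obs <- if (length(t)) max(t) - min(t) else 0
  rates <- rep(NA_real_, N)
  cvs <- rep(NA_real_, N)
  for (j in seq_len(N)) {
    tj <- t[id == j]
    if (length(tj) >= 2) {
      isi <- diff(tj)
      rates[j] <- 1000 * (length(tj) - 1) / (max(tj) - min(tj))
      cvs[j] <- stats::sd(isi) / mean(isi)
    } else if (length(tj) <= 1) {
      rates[j] <- NA_real_   # silent (or single spike): excluded
    }
  }
  active <- !is.na(rates)
  list(spikes = data.frame(t = t, id = id),
       rates = rates, cv = cvs,
       n_star = mean(active),
       r_bar = mean(rates[active]),
       cv_bar = mean(cvs[active], na.rm = TRUE),
       t_obs = t_obs)
}

#' Self-consistent mean field for the sparse inhibitory network
#'
#' Solves the population self-consistency: each active neuron (the fraction
#' `n_star` with highest excitability) receives a Poisson train of rate
#' \eqn{R_i = K n^* \bar r_0} with amplitudes from the coupling law (the
#' factor \eqn{n^*} accounts for silent presynaptic partners contributing
#' no spikes: the population-mean presynaptic rate is \eqn{n^*} times the
#' active-neuron average \eqn{\bar r_0}), and the population-average rate
#' over the active set must reproduce \eqn{\bar r_0}.  The excitability integral is discretized by
#' Gauss-Legendre nodes on the active interval; the fixed point is found by
#' damped iteration (damping 0.5) warm-started from the
#' diffusion-approximation solution.  The population-average CV follows by
#' averaging the single-neuron CV over the same nodes.
#'
#' `n_star` is an input, taken from simulation, as the active fraction is
#' not determined within this closure.
#'
#' @param cfg a [network_config()].
#' @param n_star active fraction in (0, 1].
#' @param engine `"shot"` for the exact shot-noise rate, `"da"` for the
#'   diffusion approximation inside the same fixed point.
#' @param nodes number of Gauss-Legendre nodes on the active interval.
#' @param tol fixed-point tolerance on the rate (Hz).
#' @param max_iter iteration budget.
#' @param with_cv also compute the population-average CV (slower).
#' @return object of class `mean_field_result`: list with `r_bar` (Hz),
#'   `cv_bar`, `n_star`, `Delta` (probability mass of the active set),
#'   `mu_active` (interval), `rate_profile` (data frame `mu`, `r0`),
#'   `iterations`, `residual`.
#' @export
mean_field_rate <- function(cfg, n_star = 1, engine = c("shot", "da"),
                            nodes = 24, tol = 1e-8, max_iter = 200,
                            with_cv = TRUE) {
  engine <- match.arg(engine)
  stopifnot(n_star > 0, n_star <= 1)
  nn <- cfg$neuron
  mu_lo <- cfg$mu_range[2] - n_star * diff(cfg$mu_range)
  gl <- gl01(nodes)
  mu_nodes <- mu_lo + (cfg$mu_range[2] - mu_lo) * gl$x
  wts <- gl$w            # uniform P(mu) on the active set, normalized
  m <- amp_moments(cfg$g_dist)

  rate_at <- function(mu_j, R_i) {
    if (engine == "da") {
      mu_T <- mu_j + nn$tau * (R_i / 1000) * m$mean
      s2 <- nn$tau * (R_i / 1000) * m$m2
      if (s2 <= 0) return(tonic_rate(mu_j, nn))
      da_rate(mu_T, s2, nn)
    } else {
      if (R_i <= 0) return(tonic_rate(mu_j, nn))
      lb <- laplace_bundle(nn, drive_dc(mu_j), inh_input(cfg$g_dist, R_i))
      if (lb$validity != "ok") 0 else firing_rate(lb)
    }
  }

  rhs <- function(r) {
    R_i <- cfg$K * n_star * r
    sum(wts * vapply(mu_nodes, rate_at, numeric(1), R_i = R_i))
  }

  # warm start: DA fixed point from the tonic solution
  r <- sum(wts * tonic_rate(mu_nodes, nn))
  if (engine == "shot") {
    rda <- r
    for (i in 1:60) {
      rn <- 0.5 * rda + 0.5 * {
        R_i <- cfg$K * n_star * rda
        sum(wts * vapply(mu_nodes, function(mu_j) {
          mu_T <- mu_j + nn$tau * (R_i / 1000) * m$mean
          s2 <- nn$tau * (R_i / 1000) * m$m2
          if (s2 <= 0) tonic_rate(mu_j, nn) else da_rate(mu_T, s2, nn)
        }, numeric(1)))
      }
      if (abs(rn - rda) < 1e-6) break
      rda <- rn
    }
    r <- rda
  }
  res <- Inf
  for (i in seq_len(max_iter)) {
    rn <- 0.5 * r + 0.5 * rhs(r)
    res <- abs(rn - r)
    r <- rn
    if (res < tol) break
  }
  if (res >= tol)
    stop("mean-field fixed point did not converge within max_iter")
  R_i <- cfg$K * n_star * r
  profile <- data.frame(mu = mu_nodes,
                        r0 = vapply(mu_nodes, rate_at, numeric(1),
                                    R_i = R_i))
  cv_bar <- NA_real_
  if (with_cv) {
    cv_at <- function(mu_j) {
      if (engine == "da") {
        mu_T <- mu_j + nn$tau * (R_i / 1000) * m$mean
        s2 <- nn$tau * (R_i / 1000) * m$m2
        if (s2 <= 0) return(0)
        da_cv(mu_T, s2, nn)
      } else {
        lb <- laplace_bundle(nn, drive_dc(mu_j), inh_input(cfg$g_dist, R_i))
        if (lb$validity != "ok") return(NA_real_)
        firing_stats(lb)$cv
      }
    }
    cvs <- vapply(mu_nodes, cv_at, numeric(1))
    cv_bar <- sum(wts * cvs)
  }
  structure(list(r_bar = r, cv_bar = cv_bar, n_star = n_star,
                 Delta = n_star, mu_active = c(mu_lo, cfg$mu_range[2]),
                 rate_profile = profile, iterations = i, residual = res,
                 engine = engine),
            class = "mean_field_result")
}

#' @export
print.mean_field_result <- function(x, ...) {
  cat(sprintf(
    "mean field (%s): r_bar = %.4f Hz, CV_bar = %.4f (n* = %.3f, %d iter)\n",
    x$engine, x$r_bar, x$cv_bar, x$n_star, x$iterations))
  invisible(x)
}
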