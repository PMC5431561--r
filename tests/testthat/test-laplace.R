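bundle_for <- function(dist, mu_T = 9, sigma2 = 2, kind = "dc") {
  s <- solve_drive(mu_T, sigma2, dist, lif_neuron(), kind)
  laplace_bundle(lif_neuron(), s$drive, s$inh)
}

test_that("Z0 normalization and first two voltage moments, all families x drives", {
  for (kind in c("dc", "shot")) {
    for (d in family_list()) {
      lb <- bundle_for(d, 9, 4, kind)
      expect_equal(Re(lb$logZ0(0)), 0, tolerance = 1e-12)
      # Z0'(0) = mu_T via the closed-form derivative
      expect_equal(Re(lb$dlogZ0(1e-12)), 9, tolerance = 1e-7)
      # (log Z0)''(0) = sigma2 / 2 by central difference of dlogZ0
      h <- 1e-5
      d2 <- Re(lb$dlogZ0(h) - lb$dlogZ0(-h)) / (2 * h)
      expect_equal(d2, 4 / 2, tolerance = 1e-6)
    }
  }
})

test_that("closed-form log Z0 equals generic quadrature of the kernel", {
  for (d in family_list()[c("dd", "ud", "ed")]) {
    lb <- bundle_for(d)
    Ri_ms <- lb$Ri_ms
    for (s in c(0.5, 1.5, 3, 5)) {
      quad <- stats::integrate(function(u) amp_kernel_Q(d, u, Ri_ms), 0, s,
                               rel.tol = 1e-12)$value
      expect_equal(Re(lb$logZ0(s)) - lb$mu0 * s, lb$tau * quad,
                   tolerance = 1e-8)
    }
  }
})

test_that("delta-kernel normalization constant matches exp(tau R (gamma + log|a|))", {
  # tau R_i = 2, |a_i| = 1: C0 = exp(2 * EulerGamma) ~ 3.1722
  lb <- bundle_for(amp_delta(-1), 9, 2)
  expect_equal(lb$tau * lb$Ri_ms, 2)
  s <- 30  # large s: log Z0 = mu0 s - tau R (gamma + log|a|s + E1); E1 tiny
  C0_implied <- exp(lb$mu0 * s - Re(lb$logZ0(s))) / s^(lb$tau * lb$Ri_ms)
  expect_equal(C0_implied, exp(2 * 0.5772156649015329), tolerance = 1e-6)
})

test_that("truncated-Gaussian spline log Z0 differentiates to the kernel", {
  lb <- bundle_for(amp_tgauss(-1, 0.7), 9, 2)
  h <- 1e-5
  for (s in c(0.4, 1.1, 2.7, 6)) {
    num <- (lb$logZ0(s + h) - lb$logZ0(s - h)) / (2 * h)
    expect_equal(num, lb$dlogZ0(s), tolerance = 1e-5)
  }
})

test_that("small-amplitude limit approaches the Gaussian generating function", {
  # log Z0 -> mu_T s + sigma2 s^2 / 4 pointwise as |a_i| -> 0
  lb <- bundle_for(amp_delta(-0.005), 9, 2)
  for (s in c(0.5, 1, 2))
    expect_equal(Re(lb$logZ0(s)), 9 * s + 2 * s^2 / 4, tolerance = 2e-3)
})

test_that("validity flags silent and unsupported regimes", {
  sl <- solve_drive(9, 0.5, amp_delta(-1))
  lb <- laplace_bundle(lif_neuron(), sl$drive, sl$inh)
  expect_identical(lb$validity, "silent_dc")
  expect_identical(firing_rate(lb), structure(0, silent = TRUE))
  # supra-threshold DC combined with excitatory kicks is outside the method
  lb2 <- laplace_bundle(lif_neuron(), drive_shot(12, 1, 50),
                        inh_input(amp_delta(-1), 50))
  expect_identical(lb2$validity, "unsupported_supra_dc_with_shot")
  expect_error(firing_rate(lb2), "simulator")
})

test_that("rate integrand has the documented end behaviors", {
  lb <- bundle_for(amp_delta(-1), 9, 2)
  # c -> 0 limit: v_th - v_re = 5 mV (positive-rate sign convention)
  expect_equal(shotspike:::rate_integrand(lb, 1e-10), 5, tolerance = 1e-6)
  # large-c decay ~ e^{-c(mu0 - v_th)} modulated by the kernel factor
  ratio <- shotspike:::rate_integrand(lb, 30) /
    shotspike:::rate_integrand(lb, 29)
  expect_lt(ratio, exp(-(lb$mu0 - lb$v_th) * 1) * 1.25)
})
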