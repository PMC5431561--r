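test_that("network realization honors degree, no self-connections, and seed", {
  cfg <- network_config(N = 50, K = 7, g_dist = amp_delta(-0.2))
  net <- build_network(cfg, seed = 4)
  expect_equal(dim(net$pre), c(7, 50))
  for (j in 1:50) {
    expect_false(j %in% net$pre[, j])
    expect_equal(length(unique(net$pre[, j])), 7)
  }
  expect_true(all(net$mu >= 10 & net$mu <= 11))
  net2 <- build_network(cfg, seed = 4)
  expect_identical(net, net2)
  expect_error(network_config(N = 10, K = 10, g_dist = amp_delta(-1)),
               "smaller")
})

test_that("zero coupling reduces every neuron to its tonic rate", {
  cfg <- network_config(N = 60, K = 5, g_dist = amp_delta(0))
  net <- build_network(cfg, seed = 2)
  sim <- simulate_network(net, n_spikes = 3e4, burn_spikes = 2e3)
  expect_equal(sim$n_star, 1)
  expect_equal(sim$rates, tonic_rate(net$mu), tolerance = 1e-3)
  expect_lt(max(sim$cv), 1e-8)
})

test_that("homogeneous mean field reduces to single-neuron self-consistency", {
  cfg <- network_config(N = 100, K = 10, g_dist = amp_delta(-0.3),
                        mu_range = c(10.5, 10.5 + 1e-9))
  mf <- mean_field_rate(cfg, n_star = 1, with_cv = FALSE)
  # fixed point of r = r0(R_i = K r) at mu = 10.5, solved independently
  g <- function(r) firing_rate(shot_lif(amp_delta(-0.3),
                                        drive = drive_dc(10.5),
                                        R_i = 10 * r)) - r
  r_root <- stats::uniroot(g, c(1, 40), tol = 1e-9)$root
  expect_equal(mf$r_bar, r_root, tolerance = 1e-5)
  # residual of the reported fixed point
  expect_lt(mf$residual, 1e-8)
})

test_that("mean field brackets between the extreme single-neuron rates", {
  cfg <- network_config(N = 400, K = 20, g_dist = amp_delta(-0.4))
  mf <- mean_field_rate(cfg, n_star = 0.85, with_cv = FALSE)
  R_i <- 20 * 0.85 * mf$r_bar
  r_lo <- firing_rate(shot_lif(amp_delta(-0.4),
                               drive = drive_dc(mf$mu_active[1]), R_i = R_i))
  r_hi <- firing_rate(shot_lif(amp_delta(-0.4),
                               drive = drive_dc(mf$mu_active[2]), R_i = R_i))
  expect_gte(mf$r_bar, r_lo)
  expect_lte(mf$r_bar, r_hi)
})

test_that("mean field matches direct simulation within a few percent", {
  cfg <- network_config(N = 400, K = 20, g_dist = amp_delta(-0.4))
  net <- build_network(cfg, seed = 11)
  sim <- simulate_network(net, n_spikes = 1.5e5, burn_spikes = 3e4)
  mf <- mean_field_rate(cfg, n_star = sim$n_star, with_cv = FALSE)
  expect_lt(abs(mf$r_bar - sim$r_bar) / sim$r_bar, 0.06)
})

test_that("rate falls with coupling strength and the DA overestimates it", {
  r <- vapply(c(0.1, 0.4, 1), function(am)
    mean_field_rate(network_config(400, 20, amp_delta(-am)),
                    n_star = 0.85, with_cv = FALSE)$r_bar, numeric(1))
  expect_true(all(diff(r) < 0))
  for (am in c(0.5, 1)) {
    cfg <- network_config(400, 20, amp_delta(-am))
    r_shot <- mean_field_rate(cfg, n_star = 0.85, with_cv = FALSE)$r_bar
    r_da <- mean_field_rate(cfg, n_star = 0.85, engine = "da",
                            with_cv = FALSE)$r_bar
    expect_gt(r_da, r_shot)
  }
})

test_that("delta couplings pile more mass at low rates than exponential ones", {
  am <- 0.4
  seeds <- 11
  lowbin <- function(g_dist) {
    net <- build_network(network_config(400, 20, g_dist), seed = seeds)
    sim <- simulate_network(net, n_spikes = 1.2e5, burn_spikes = 3e4)
    r <- sim$rates[!is.na(sim$rates)]
    mean(r < 4)   # mass of the lowest-rate bin, active neurons
  }
  expect_gte(lowbin(amp_delta(-am)), lowbin(amp_exponential(-am)))
})

test_that("doubling the spike budget leaves the population rate unchanged", {
  cfg <- network_config(N = 200, K = 10, g_dist = amp_delta(-0.3))
  net <- build_network(cfg, seed = 6)
  s1 <- simulate_network(net, n_spikes = 5e4, burn_spikes = 1e4)
  s2 <- simulate_network(net, n_spikes = 1e5, burn_spikes = 1e4)
  expect_equal(s1$r_bar, s2$r_bar, tolerance = 0.05)
})
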