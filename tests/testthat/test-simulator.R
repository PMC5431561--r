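test_that("noiseless supra-threshold neuron fires perfectly periodically", {
  m <- shot_lif(amp_delta(-1), drive = drive_dc(12), R_i = 0)
  st <- simulate_neuron(m, n_spikes = 500, seed = 1)
  isi <- diff(st)
  expect_equal(mean(isi), 1000 / tonic_rate(12), tolerance = 1e-10)
  expect_lt(stats::sd(isi), 1e-10)
  s <- isi_stats(st)
  expect_equal(s$r0, tonic_rate(12), tolerance = 1e-10)
  expect_equal(s$cv, 0, tolerance = 1e-10)
})

test_that("sub-threshold DC with pure inhibition raises as silent", {
  m <- shot_lif(amp_delta(-1), drive = drive_dc(9), R_i = 100)
  expect_error(simulate_neuron(m, n_spikes = 10, max_events = 1e5),
               "silent")
})

test_that("same seed gives identical spike trains", {
  m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)
  a <- simulate_neuron(m, n_spikes = 2000, seed = 33)
  b <- simulate_neuron(m, n_spikes = 2000, seed = 33)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("isi_stats recovers the exponential (Poisson) law", {
  set.seed(5)
  train <- cumsum(stats::rexp(5e4, rate = 1 / 50))  # mean ISI 50 ms
  s <- isi_stats(train)
  expect_lt(abs(s$cv - 1), 3 * s$se_cv)
  expect_lt(abs(s$r0 - 20), 3 * s$se_r0)
})

test_that("rate estimates from the two halves of a run are compatible", {
  m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)
  st <- simulate_neuron(m, n_spikes = 40000, seed = 8)
  h1 <- isi_stats(st[1:20000])
  h2 <- isi_stats(st[20001:40000])
  z <- abs(h1$r0 - h2$r0) / sqrt(h1$se_r0^2 + h2$se_r0^2)
  expect_lt(z, 4)
})

test_that("theory matches simulation within 3 SE across families and drives", {
  set.seed(99)
  cases <- list(
    list(d = amp_delta(-1), s2 = 2, kind = "dc"),
    list(d = amp_delta(-0.1), s2 = 2, kind = "dc"),
    list(d = amp_uniform(-2, 0), s2 = 4, kind = "dc"),
    list(d = amp_tgauss(-1, 2), s2 = 4, kind = "dc"),
    list(d = amp_exponential(-1), s2 = 4, kind = "dc"),
    list(d = amp_exponential(-1), s2 = 2, kind = "shot"),
    list(d = amp_tgauss(-tg_cal, tg_cal), s2 = 4, kind = "shot"))
  for (cs in cases) {
    m <- shot_lif(cs$d, mu_T = 9, sigma2 = cs$s2, drive_kind = cs$kind)
    fs <- firing_stats(m)
    ss <- isi_stats(simulate_neuron(m, n_spikes = 1e5))
    expect_lt(abs(fs$r0 - ss$r0), 3 * ss$se_r0)
    expect_lt(abs(fs$cv - ss$cv), 3 * ss$se_cv)
  }
})

test_that("binned-count spectrum of a periodic train has lines at the rate", {
  m <- shot_lif(amp_delta(-1), drive = drive_dc(12), R_i = 0)
  sp <- spectrum_estimate(m, n_realizations = 2, duration_s = 8, seed = 3)
  f0 <- tonic_rate(12)
  # spectral lines at the firing rate and its harmonics, far above background
  line <- function(k) max(sp$C_hat[abs(sp$f_hz - k * f0) < 1])
  background <- stats::median(sp$C_hat)
  for (k in 1:3) expect_gt(line(k), 50 * background)
  near <- abs(sp$f_hz - f0) < 2
  expect_lt(abs(sp$f_hz[near][which.max(sp$C_hat[near])] - f0), 0.5)
})

test_that("averaging over more realizations reduces spectral variance", {
  m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)
  v <- vapply(c(4, 16), function(nr) {
    sp <- spectrum_estimate(m, n_realizations = nr, duration_s = 8,
                            seed = 20 + nr)
    keep <- sp$f_hz >= 60 & sp$f_hz <= 90
    th <- spike_spectrum(m, sp$f_hz[keep])
    mean((sp$C_hat[keep] - th$C_hat)^2)
  }, numeric(1))
  expect_lt(v[2], v[1])
})
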