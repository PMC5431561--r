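test_that("shot-noise rate and CV reach the diffusion limit for small kicks", {
  m <- shot_lif(amp_delta(-0.01), mu_T = 9, sigma2 = 2)
  fs <- firing_stats(m)
  expect_equal(fs$r0, da_rate(9, 2), tolerance = 5e-3)
  expect_equal(fs$cv, da_cv(9, 2), tolerance = 5e-3)
})

test_that("sub-threshold DC with pure inhibition never fires", {
  m <- shot_lif(amp_delta(-1), drive = drive_dc(9), R_i = 100)
  expect_equal(firing_rate(m), 0, ignore_attr = TRUE)
  expect_true(is.na(firing_stats(m)$cv))
})

test_that("rate grows with noise and falls with kick size at matched input", {
  r_sig <- vapply(c(1, 2, 4), function(s2)
    firing_rate(shot_lif(amp_delta(-1), mu_T = 9, sigma2 = s2)), numeric(1))
  expect_true(all(diff(r_sig) > 0))
  r_amp <- vapply(c(0.1, 0.5, 1, 2), function(a)
    firing_rate(shot_lif(amp_delta(-a), mu_T = 9, sigma2 = 2)), numeric(1))
  expect_true(all(diff(r_amp) < 0))
})

test_that("longer-tailed amplitude laws fire slower at matched (mu_T, sigma2, mean)", {
  fams <- family_list()
  r <- vapply(fams, function(d)
    firing_rate(shot_lif(d, mu_T = 9, sigma2 = 4)), numeric(1))
  expect_true(r[["ed"]] <= r[["tgd"]])
  expect_true(r[["tgd"]] <= r[["dd"]])
})

test_that("CV exhibits coherence resonance in the noise intensity", {
  # the minimum sits at larger noise for longer-tailed laws; bracket each
  grids <- list(list(d = amp_delta(-1), s2 = c(1.2, 2.8, 10)),
                list(d = amp_exponential(-1), s2 = c(2.6, 6, 25)))
  for (g in grids) {
    cv <- vapply(g$s2, function(s2)
      firing_stats(shot_lif(g$d, mu_T = 9, sigma2 = s2))$cv, numeric(1))
    expect_lt(cv[2], cv[1])
    expect_lt(cv[2], cv[3])
  }
})

test_that("CV has an interior minimum along the kick-amplitude sweep", {
  ai <- seq(0.3, 1.6, by = 0.1)
  cv <- vapply(ai, function(a)
    firing_stats(shot_lif(amp_delta(-a), mu_T = 9, sigma2 = 2))$cv,
    numeric(1))
  i <- which.min(cv)
  expect_gt(i, 1)
  expect_lt(i, length(ai))
})

test_that("first-passage transform behaves like a probability transform", {
  m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)
  fs <- firing_stats(m)
  f <- c(0.05, seq(2, 80, by = 2))
  sp <- spike_spectrum(m, f)
  q <- complex(real = sp$q_re, imaginary = sp$q_im)
  expect_true(all(Mod(q) <= 1 + 1e-10))
  expect_equal(Mod(q[1]), 1, tolerance = 1e-3)          # q^(0+) -> 1
  # first-moment identity: Im q^(omega)/omega -> -<t> as omega -> 0
  w1 <- 2 * pi * f[1] / 1000
  expect_equal(Im(q[1]) / w1, -fs$mean_isi, tolerance = 1e-2)
  expect_true(all(sp$C_hat >= 0))
})

test_that("spectrum plateaus equal {r0 CV^2, r0} as a set", {
  m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)
  fs <- firing_stats(m)
  sp <- spike_spectrum(m, c(0.02, 900))
  plateaus <- sort(sp$C_hat)
  expect_equal(plateaus, sort(c(fs$r0 * fs$cv^2, fs$r0)), tolerance = 0.01)
})

test_that("rotated-contour and real-axis spike-triggered rates agree", {
  lb <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)$lf
  w <- c(0.35, 0.5, 0.6) # omega tau in [7, 12]: both methods accurate
  a <- shotspike:::rho_real_axis(lb, w)
  b <- shotspike:::rho_rotated(lb, w)
  expect_lt(max(Mod(a - b) / Mod(b)), 1e-5)
})

test_that("reconstructed ISI density is a probability density with the right mean", {
  for (a in c(0.1, 1)) {
    m <- shot_lif(amp_delta(-a), mu_T = 9, sigma2 = 2)
    fs <- firing_stats(m)
    d <- isi_density(m)
    dt <- diff(d$t_ms[1:2])
    mass <- attr(d, "atom_mass") + sum(d$q) * dt
    expect_equal(mass, 1, tolerance = 1e-3)
    mean_t <- attr(d, "atom_mass") * attr(d, "atom_time_ms") +
      sum(d$q * d$t_ms) * dt
    expect_equal(mean_t, fs$mean_isi, tolerance = 0.01)
    expect_gt(min(d$q), -1e-3 * max(d$q))   # non-negative up to ripple
  }
})

test_that("the deterministic atom carries the no-kick probability", {
  m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)  # mu0 = 11, R_i = 100 Hz
  d <- isi_density(m)
  tstar <- 20 * log((11 - 5) / (11 - 10))
  expect_equal(attr(d, "atom_time_ms"), tstar, tolerance = 1e-10)
  expect_equal(attr(d, "atom_mass"), exp(-0.1 * tstar), tolerance = 1e-12)
})

test_that("ISI concentration shifts to longer periods for larger kicks", {
  p_small <- isi_peak(shot_lif(amp_delta(-0.1), mu_T = 9, sigma2 = 2))
  p_large <- isi_peak(shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2))
  expect_lt(p_small$spectral_period_ms, p_large$spectral_period_ms)
  expect_lt(p_small$mode_ms, p_large$mode_ms)
})
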