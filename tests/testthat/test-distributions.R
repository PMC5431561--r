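test_that("closed-form moments agree with quadrature for every density family", {
  cases <- list(amp_exponential(-1), amp_exponential(-0.3),
                amp_uniform(-2, 0), amp_uniform(-1.7, -0.2),
                amp_tgauss(-1, 0.5), amp_tgauss(-1, 5),
                amp_tgauss(-0.7766, 0.7766), amp_tgauss(-0.2, 2.5))
  for (d in cases) {
    qm <- quad_moments(d)
    cm <- amp_moments(d)
    expect_equal(qm$mass, 1, tolerance = 1e-8)
    expect_equal(cm$mean, qm$mean, tolerance = 1e-7)
    expect_equal(cm$var, qm$var, tolerance = 1e-7)
    expect_equal(cm$skewness, qm$skewness, tolerance = 1e-6)
  }
})

test_that("reference moment values are reproduced", {
  # exponential: |skewness| = 2, sd = mean magnitude
  ed <- amp_moments(amp_exponential(-1))
  expect_equal(ed$mean, -1)
  expect_equal(sqrt(ed$var), 1)
  expect_equal(ed$skewness, -2)
  # delta: no variability
  dd <- amp_moments(amp_delta(-1))
  expect_equal(dd$var, 0)
  expect_equal(dd$skewness, 0)
  # truncated Gaussian skewness at narrow and wide widths
  expect_equal(amp_moments(amp_tgauss(-1, 0.5))$skewness, -0.22,
               tolerance = 0.005)
  expect_equal(amp_moments(amp_tgauss(-1, 5))$skewness, -0.92,
               tolerance = 0.005)
  # wide-width limit of the skewness: -sqrt(2)(4-pi)/(pi-2)^{3/2}
  lim <- -sqrt(2) * (4 - pi) / (pi - 2)^1.5
  expect_equal(amp_moments(amp_tgauss(-1, 5e4))$skewness, lim,
               tolerance = 1e-4)
  # calibrated equal-peak-and-width truncated Gaussian: mean -1, sd ~0.616
  cc <- tgauss_calibrate(-1)
  expect_equal(cc, 0.7766, tolerance = 1e-4)
  tg <- amp_moments(amp_tgauss(-cc, cc))
  expect_equal(tg$mean, -1, tolerance = 1e-10)
  expect_equal(sqrt(tg$var), 0.6163, tolerance = 1e-3)
})

test_that("samplers draw from the right law", {
  set.seed(101)
  n <- 2e5
  for (d in family_list()) {
    x <- amp_sample(d, n)
    expect_length(x, n)
    m <- amp_moments(d)
    se <- sqrt(max(m$var, 1e-30) / n)
    expect_lt(abs(mean(x) - m$mean), 5 * se + 1e-12)
    if (m$var > 0)
      expect_lt(abs(stats::var(x) - m$var) / m$var, 0.05)
  }
  expect_identical(amp_sample(amp_delta(-0.5), 5), rep(-0.5, 5))
  u <- amp_sample(amp_uniform(-2, 0), 1e4)
  expect_true(all(u >= -2 & u <= 0))
  tg <- amp_sample(amp_tgauss(-1, 2), 1e4)
  expect_true(all(tg <= 0))
})

test_that("Laplace kernels have the right values and small-s limit", {
  # hand-evaluated delta kernel: -R (1 - e^{s a})/s
  expect_equal(amp_kernel_Q(amp_delta(-1), 1, rate = 0.1),
               -0.1 * (1 - exp(-1)), tolerance = 1e-12)
  # Q(s)/R -> <a> as s -> 0+, every family
  for (d in family_list()) {
    m <- amp_moments(d)
    expect_equal(amp_kernel_Q(d, 1e-9, rate = 1), m$mean, tolerance = 1e-7)
    # second-order Taylor consistency at moderate small s
    q <- amp_kernel_Q(d, 1e-4, rate = 1)
    expect_equal(q, m$mean + 1e-4 * m$m2 / 2, tolerance = 1e-6)
  }
  # excitatory exponential: pole guarded
  expect_error(amp_kernel_Q(amp_exponential(1), 1.5, rate = 1), "pole")
})

test_that("truncated-Gaussian kernel matches the asymptotic erfc expansion", {
  # wide-width, s > 1 regime where the first-order erfc expansion applies
  d <- amp_tgauss(-1, 2)
  s <- 3; R <- 0.05
  q_full <- amp_kernel_Q(d, s, rate = R)
  sg <- 2; ap <- -1
  phi0 <- pnorm(-ap / sg)
  tail_term <- sg * exp(-ap^2 / (2 * sg^2)) / (sqrt(2 * pi) * (sg^2 * s + ap))
  q_asym <- -(R / (phi0 * s)) * (phi0 - tail_term)
  expect_equal(q_full, q_asym, tolerance = 0.01)
})

test_that("kernel integrals differentiate back to the kernel", {
  for (d in family_list()[c("dd", "ud", "ed")]) {
    s <- c(0.3, 1.2, 4)
    h <- 1e-5
    num <- (amp_kernel_int(d, s + h, 0.1) - amp_kernel_int(d, s - h, 0.1)) /
      (2 * h)
    expect_equal(num, amp_kernel_Q(d, s, 0.1), tolerance = 1e-7)
  }
})

test_that("distribution spec strings round-trip", {
  specs <- c("delta:a_i=-1", "exp:a=-1", "uniform:l1=-2,l2=0",
             "tgauss:ap=-0.7766,sg=0.7766")
  for (sp in specs) {
    d <- parse_amp_dist(sp)
    expect_s3_class(d, "amp_dist")
    d2 <- parse_amp_dist(shotspike:::amp_spec_string(d))
    expect_equal(amp_moments(d2), amp_moments(d))
  }
  expect_error(parse_amp_dist("lognormal:mu=1"), "unknown")
})
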