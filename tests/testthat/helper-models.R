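# Shared fixtures: the four amplitude families at matched mean |<a_i>| = 1 mV
# (truncated Gaussian calibrated so a_p = sigma_G with mean -1).
tg_cal <- 0.7766
family_list <- function(mean_mag = 1) {
  cc <- tg_cal * mean_mag
  list(dd = amp_delta(-mean_mag),
       ud = amp_uniform(-2 * mean_mag, 0),
       tgd = amp_tgauss(-cc, cc),
       ed = amp_exponential(-mean_mag))
}

# numeric quadrature moments of a density-bearing amplitude law
quad_moments <- function(dist, lower = -Inf) {
  mk <- function(k) stats::integrate(function(a) a^k * amp_density(dist, a),
                                     lower, 0, rel.tol = 1e-12)$value
  m1 <- mk(1); m2 <- mk(2); m3 <- mk(3)
  v <- m2 - m1^2
  list(mass = stats::integrate(function(a) amp_density(dist, a), lower, 0,
                               rel.tol = 1e-12)$value,
       mean = m1, var = v, skewness = (m3 - 3 * m1 * v - m1^3) / v^1.5)
}
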