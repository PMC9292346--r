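test_that("cyclotron frequency follows qB/m", {
  spec <- ion_cloud_spec()  # B = 7 T, m/z = 500
  wc <- cyclotron_frequency(spec)
  expect_equal(wc, 1.35081e6, tolerance = 1e-4)
  expect_identical(cyclotron_frequency(ion_cloud_spec(B = 0)), 0)
  expect_equal(cyclotron_frequency(ion_cloud_spec(B = 14)), 2 * wc)
  ## doubly charged ion at the same m/z has the same frequency
  expect_equal(cyclotron_frequency(ion_cloud_spec(charge_number = 2)), wc)
})

test_that("frequency identities hold to 1e-12 relative for stable wells", {
  spec <- ion_cloud_spec()
  wc <- cyclotron_frequency(spec)
  crit <- (wc / 2)^2 * spec$m / spec$q
  set.seed(42)
  for (A20 in c(0, 10^runif(25, 0, log10(0.99 * crit)))) {
    fs <- eigenfrequencies(A20, spec)
    expect_lt(abs(2 * fs$omega_plus * fs$omega_minus - fs$omega_z^2),
              1e-12 * max(fs$omega_z^2, fs$omega_c^2 * 1e-20))
    expect_lt(abs(fs$omega_c^2 -
                  (fs$omega_plus^2 + fs$omega_minus^2 + fs$omega_z^2)),
              1e-12 * fs$omega_c^2)
  }
  ## free-space limit
  fs0 <- eigenfrequencies(0, spec)
  expect_identical(fs0$omega_plus, wc)
  expect_identical(fs0$omega_minus, 0)
  expect_identical(fs0$omega_z, 0)
  ## stability boundary reported with the critical strength
  expect_error(eigenfrequencies(1.01 * crit, spec), "critical")
})

test_that("magnetron frequency scales as 1/B in the weak-well limit", {
  A20 <- 4300
  w1 <- eigenfrequencies(A20, ion_cloud_spec(B = 7))$omega_minus
  w2 <- eigenfrequencies(A20, ion_cloud_spec(B = 14))$omega_minus
  expect_equal(w1 / w2, 2, tolerance = 1e-3)
})

test_that("local reduced frequency reduces to the ideal-field value", {
  spec <- ion_cloud_spec()
  d <- 0.01
  fit <- fit_harmonics(synthetic_harmonic_field(0.2, 4300, 0, 0), d = d)
  wp <- local_reduced_frequency(fit, c(0, 0.004, 0.008), c(0, 0.005, -0.008), spec)
  expect_equal(max(wp) - min(wp), 0)
  expect_equal(wp[1], eigenfrequencies(4300, spec)$omega_plus)
  ## a pure positive A40 perturbation lowers omega_+ with growing z^2
  fit4 <- fit_harmonics(synthetic_harmonic_field(0, 4300, 1e7, 0), d = d)
  wz <- local_reduced_frequency(fit4, 0.006, c(0, 0.004, 0.008), spec)
  expect_true(all(diff(wz) < 0))
  ## local instability is reported with the offending location
  fit_bad <- fit_harmonics(synthetic_harmonic_field(0, 4300, 5e11, 0), d = d)
  expect_error(local_reduced_frequency(fit_bad, 0.001, 0.02, spec), "unstable")
})

test_that("comet time equals 2*pi over the constructed frequency spread", {
  spec <- ion_cloud_spec()
  d <- 0.01
  fit <- fit_harmonics(synthetic_harmonic_field(0, 4300, 1e7, -1e9), d = d)
  rho <- seq(spec$r_excitation - spec$r_cloud,
             spec$r_excitation + spec$r_cloud, length.out = 121)
  z <- seq(-spec$z_cloud, spec$z_cloud, length.out = 161)
  wp <- local_reduced_frequency(fit, rep(rho, times = 161),
                                rep(z, each = 121), spec)
  expect_identical(comet_time(fit, spec), 2 * pi / (max(wp) - min(wp)))
  ## ideal field: no dephasing
  fit0 <- fit_harmonics(synthetic_harmonic_field(0.5, 4300, 0, 0), d = d)
  expect_identical(comet_time(fit0, spec), Inf)
  ## adding a constant to the potential changes nothing
  fitC <- fit_harmonics(synthetic_harmonic_field(17, 4300, 1e7, -1e9), d = d)
  expect_equal(comet_time(fitC, spec), comet_time(fit, spec), tolerance = 1e-12)
  ## doubling the anharmonic content halves the comet time (linearization
  ## of the square root; exact as the perturbation shrinks)
  fa <- fit_harmonics(synthetic_harmonic_field(0, 4300, 1e6, -1e8), d = d)
  fb <- fit_harmonics(synthetic_harmonic_field(0, 4300, 2e6, -2e8), d = d)
  expect_equal(comet_time(fa, spec) / comet_time(fb, spec), 2,
               tolerance = 2e-3)
})

test_that("bisection of the orthogonality factor is bracket-order invariant", {
  sp <- 0.0127 / 48
  r1 <- find_orthogonal_ratio("hyperbolic_compensated", c(1.0, 1.4),
                              rel_tol = 5e-3, spacing = sp, tol = 1e-8)
  r2 <- find_orthogonal_ratio("hyperbolic_compensated", c(1.4, 1.0),
                              rel_tol = 5e-3, spacing = sp, tol = 1e-8)
  expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-6)
  expect_equal(as.numeric(r1), 1.16, tolerance = 0.05)
  ## gamma changes sign across the root
  g_lo <- orthogonality_gamma("hyperbolic_compensated", 1.0, spacing = sp,
                              tol = 1e-8)
  g_hi <- orthogonality_gamma("hyperbolic_compensated", 1.4, spacing = sp,
                              tol = 1e-8)
  expect_lt(as.numeric(g_lo) * as.numeric(g_hi), 0)
  expect_error(find_orthogonal_ratio("hyperbolic_compensated", c(1.3, 1.4),
                                     spacing = sp, tol = 1e-8),
               "sign")
})
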