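test_that("dipolar cylinder spectrum has odd orders with the printed amplitudes", {
  lay <- detection_layout(half_angle = pi / 2)
  sp <- cylinder_harmonics(0.5, lay, n_max = 5)
  expect_identical(sp$orders, c(1, 3, 5, 7, 9))
  ## fundamental: 2 * sin(pi/2) / pi * 0.5 = 1/pi
  expect_equal(sp$amplitudes[1], 1 / pi)
  ## 120-degree electrodes null the third harmonic exactly
  sp120 <- cylinder_harmonics(0.5, detection_layout(pi / 3), n_max = 3)
  expect_identical(sp120$amplitudes[2], 0)
  expect_gt(abs(sp120$amplitudes[1]), 0)
  ## adjacent odd-order amplitude ratio scales as (rho/R)^2
  r1 <- cylinder_harmonics(0.3, lay)$amplitudes
  r2 <- cylinder_harmonics(0.6, lay)$amplitudes
  expect_equal((r1[2] / r1[1]) / (r2[2] / r2[1]), (0.3 / 0.6)^2,
               tolerance = 1e-12)
  ## amplitudes decay with order for rho/R < 1
  expect_true(all(diff(abs(sp$amplitudes)) < 0))
  expect_error(cylinder_harmonics(1.0, lay), "rho_over_R")
})

test_that("alternating multielectrode wiring multiplies the detected frequency", {
  two <- detection_layout(pi / 8, n_pairs = 2)
  sp2 <- multielectrode_harmonics(0.5, two, n_max = 3)
  expect_identical(sp2$orders, c(2, 6, 10))
  expect_equal(sp2$amplitudes[1], 4 * sin(2 * pi / 8) / (2 * pi) * 0.5^2)
  four <- detection_layout(pi / 16, n_pairs = 4)
  sp4 <- multielectrode_harmonics(0.5, four, n_max = 3)
  expect_identical(sp4$orders[1], 4)  # eight electrodes: main harmonic 4 w+
  ## an unexcited ion (rho = 0) induces no differential signal
  expect_true(all(multielectrode_harmonics(0, two)$amplitudes == 0))
  expect_error(detection_layout(pi / 2, n_pairs = 2), "half_angle")
  expect_error(multielectrode_harmonics(0.5, detection_layout(pi / 8, 2, FALSE)),
               "alternating")
})

test_that("reciprocity gives -q inside a closed unit-voltage boundary and superposes", {
  pg <- solve_laplace(constant_box_grid(v = 1), tol = 1e-10)
  q <- 1.602176634e-19
  qq <- reciprocity_charge(pg, q, rbind(c(0.003, 0), c(0.006, 0.002)))
  expect_equal(qq, rep(-q, 2), tolerance = 1e-7)
  ## superposition: two ions induce the sum of their individual charges
  expect_equal(sum(qq), reciprocity_charge(pg, 2 * q, c(0.0045, 0.001)),
               tolerance = 1e-7)
  expect_error(reciprocity_charge(pg, q, c(0.02, 0)), "outside")
})

test_that("weight-field reciprocity matches the closed-form cylinder harmonics", {
  R <- 0.0127
  pg <- solve_laplace(segment_cylinder_grid(R = R, alpha = pi / 4), tol = 1e-9)
  th <- (0:255) * 2 * pi / 256
  for (frac in c(0.3, 0.5)) {
    pos <- cbind(frac * R * cos(th), frac * R * sin(th), 0)
    ## differential charge between the two opposite segments (q = 1); the
    ## opposite segment's weight field is the solved one rotated by pi
    dq <- reciprocity_charge(pg, 1, pos) -
      reciprocity_charge(pg, 1, cbind(-pos[, 1], -pos[, 2], 0))
    amps <- vapply(1:5, function(k) 2 * mean(dq * cos(k * th)), 0)
    cf <- cylinder_harmonics(frac, detection_layout(pi / 4), n_max = 3)
    ## centred orbit: even orders absent
    expect_lt(max(abs(amps[c(2, 4)])), 1e-3 * abs(amps[1]))
    ## first three odd orders agree within 2% (relative to the fundamental)
    expect_rel(amps[3] / amps[1], cf$amplitudes[2] / cf$amplitudes[1], 0.02)
    expect_rel(amps[5] / amps[1], cf$amplitudes[3] / cf$amplitudes[1], 0.05)
    ## absolute scale: differential signal is twice the single-ended form
    expect_rel(abs(amps[1]), 2 * cf$amplitudes[1], 0.02)
    ## total differential charge bounded by the ion charge
    expect_lt(max(abs(dq)), 1)
  }
  ## ion at the symmetry centre induces no differential charge
  expect_equal(reciprocity_charge(pg, 1, c(0, 0, 0)) -
                 reciprocity_charge(pg, 1, c(0, 0, 0)), 0)
})

test_that("synthesized transients peak at the predicted harmonic orders", {
  wp <- 2 * pi * 1e5
  lay <- detection_layout(pi / 3)
  sp <- cylinder_harmonics(0.5, lay, n_max = 4)
  tr <- synthesize_transient(sp, wp, duration = 2e-3, sample_rate = 4e6)
  peak_at <- function(order) {
    idx <- which.min(abs(tr$freq - order * wp / (2 * pi)))
    max(tr$magnitude[max(1, idx - 2):(idx + 2)])
  }
  expect_gt(peak_at(1), 100 * peak_at(3))  # third harmonic nulled
  expect_gt(peak_at(5), 5 * peak_at(3))
  ## single-order spectrum: one clean line
  single <- structure(list(orders = 2, amplitudes = 1, rho_over_R = 0.5,
                           half_angle = pi / 3, n_pairs = 1),
                      class = "harmonic_spectrum")
  ts <- synthesize_transient(single, wp, 2e-3, 2e6)
  expect_equal(ts$freq[which.max(ts$magnitude)], 2 * wp / (2 * pi),
               tolerance = 1e-2)
  ## two-pair layout: dominant line at 2 w+
  sp2 <- multielectrode_harmonics(0.5, detection_layout(pi / 8, 2), n_max = 3)
  t2 <- synthesize_transient(sp2, wp, 2e-3, 8e6)
  expect_equal(t2$freq[which.max(t2$magnitude)], 2 * wp / (2 * pi),
               tolerance = 1e-2)
  expect_error(synthesize_transient(sp2, wp, 1e-3, 1e6), "aliasing")
})
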