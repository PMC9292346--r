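test_that("closed-cylinder series matches an independent Bessel-J oracle", {
  tr <- make_trap("cylindrical", list(R = 0.0127, z0 = 0.0127, v_trap = 1))
  pts_r <- c(0, 0.002, 0.005, 0.008, 0, 0.004)
  pts_z <- c(0, 0.001, -0.004, 0.006, 0.009, -0.008)
  mine <- trapping_potential("cylindrical", tr, pts_r, 0, pts_z)
  oracle <- cyl_potential_jform(pts_r, pts_z, 0.0127, 0.0127)
  expect_lt(max(abs(mine - oracle)), 1e-8)
  ## centre potential in units of the trapping voltage
  expect_equal(mine[1], 0.2787, tolerance = 1e-3 / 0.2787)
})

test_that("near-center expansion reproduces the known numerical coefficients", {
  tr <- make_trap("cylindrical", list(R = 0.0127, z0 = 0.0127, v_trap = 1))
  ce <- center_expansion("cylindrical", tr)
  expect_equal(ce$gamma, 0.2787, tolerance = 2e-4 / 0.2787)
  expect_equal(ce$alpha_coef, 2.8404, tolerance = 2e-4)
  ## consistent with a quadratic fit in a ball of radius a/20
  a <- ce$a
  pts <- expand.grid(r = seq(0, a / 20, length.out = 7),
                     z = seq(-a / 20, a / 20, length.out = 9))
  phi <- trapping_potential("cylindrical", tr, pts$r, 0, pts$z)
  cf <- qr.solve(cbind(1, pts$z^2 - pts$r^2 / 2), phi)
  expect_equal(cf[[1]], ce$gamma, tolerance = 1e-3)
  expect_equal(cf[[2]] * a^2, ce$alpha_coef, tolerance = 1e-2)
  ## cubic cell: gamma = 1/3 by symmetry (six faces), alpha ~ 2.7737
  cec <- center_expansion("cubic", make_trap("cubic"))
  expect_equal(cec$gamma, 1 / 3, tolerance = 1e-10)
  expect_equal(cec$alpha_coef, 2.77373, tolerance = 1e-4)
})

test_that("ideal potential is exact and boundary values are honoured", {
  ip <- ideal_field_params(alpha = 1, chi = 0)
  expect_identical(trapping_potential("ideal", ip, 0, 0, 0.001), 1e-6)
  ## cubic Dirichlet condition: near the centre of a trapping plate
  cub <- make_trap("cubic")
  a <- cub$params$a
  v <- trapping_potential("cubic", cub, 0, 0, 0.499 * a,
                          trunc = series_truncation(4000, 1e-9))
  expect_equal(v, cub$params$v_trap, tolerance = 1e-2)
  ## cylindrical side wall is grounded
  cyl <- make_trap("cylindrical")
  v2 <- trapping_potential("cylindrical", cyl, 0.9995 * cyl$params$R, 0, 0.003,
                           trunc = series_truncation(20000, 1e-8))
  expect_lt(abs(v2), 5e-3 * cyl$params$v_trap)
})

test_that("analytic potentials satisfy the discrete Laplacian to O(h^2)", {
  cyl <- make_trap("cylindrical")
  defect_at <- function(h) {
    rho <- seq(0, 40 * h, by = h)
    z <- seq(-40 * h, 40 * h, by = h)
    phi <- outer(rho, z, function(r, zz)
      trapping_potential("cylindrical", cyl, r, 0, zz))
    mask <- matrix(0L, length(rho), length(z))
    mask[length(rho), ] <- 1L; mask[, 1] <- 1L; mask[, length(z)] <- 1L
    icrcell:::laplace_defect_axisym_cpp(phi, mask, h, h)
  }
  d1 <- defect_at(1e-4); d2 <- defect_at(5e-5)
  expect_lt(d1, 1e-6)
  expect_gt(d1 / d2, 3)  # second-order convergence
})

test_that("potentials are linear in the driving voltage and have the right parity", {
  cyl1 <- make_trap("cylindrical", list(v_trap = 1))
  cyl3 <- make_trap("cylindrical", list(v_trap = 3))
  expect_equal(trapping_potential("cylindrical", cyl3, 0.004, 0, 0.005),
               3 * trapping_potential("cylindrical", cyl1, 0.004, 0, 0.005))
  ## trapping potentials even in z
  expect_equal(trapping_potential("cylindrical", cyl1, 0.004, 0, 0.006),
               trapping_potential("cylindrical", cyl1, 0.004, 0, -0.006))
  par <- make_trap("paracell")
  expect_equal(trapping_potential("paracell_full", par, 0.004, 0.002, 0.007),
               trapping_potential("paracell_full", par, 0.004, 0.002, -0.007))
  ## dipolar potentials odd in x
  cub <- make_trap("cubic")
  xs <- c(0.002, 0.005, 0.009)
  expect_equal(excitation_potential("cubic_dipolar", cub, -xs, 0.001, 0.002),
               -excitation_potential("cubic_dipolar", cub, xs, 0.001, 0.002))
  expect_identical(excitation_potential("cubic_dipolar", cub, 0, 0.003, 0.002), 0)
  expect_equal(excitation_potential("cylindrical_dipolar", cyl1, -xs, 0.001, 0.002),
               -excitation_potential("cylindrical_dipolar", cyl1, xs, 0.001, 0.002))
})

test_that("cubic dipolar near-center slope gives beta1 ~ 0.721", {
  cub <- make_trap("cubic")
  a <- cub$params$a
  h <- a / 1000
  slope <- (excitation_potential("cubic_dipolar", cub, h, 0, 0) -
            excitation_potential("cubic_dipolar", cub, -h, 0, 0)) / (2 * h)
  expect_equal(slope * a, 0.721, tolerance = 2e-3)
})

test_that("cylindrical dipolar axial ripple vanishes for long cells", {
  ripple <- function(aspect) {
    cyl <- make_trap("cylindrical", list(z0 = 0.0127 * aspect))
    v <- excitation_potential("cylindrical_dipolar", cyl, 0.005, 0.001,
                              seq(-0.005, 0.005, length.out = 11))
    max(v) - min(v)
  }
  r1 <- ripple(1); r4 <- ripple(4); r8 <- ripple(8)
  expect_gt(r1, r4)
  expect_gt(r4, r8)
  ## the long-cell limit approaches the infinite-cylinder (z-free) form
  cyl8 <- make_trap("cylindrical", list(z0 = 0.0127 * 8))
  v_mid <- excitation_potential("cylindrical_dipolar", cyl8, 0.005, 0.001, 0,
                                v_dipolar = 2)
  w <- infinite_cylinder_segment_potential(sqrt(0.005^2 + 0.001^2) / 0.0127,
                                           atan2(0.001, 0.005), pi / 4) -
    infinite_cylinder_segment_potential(sqrt(0.005^2 + 0.001^2) / 0.0127,
                                        atan2(0.001, 0.005) - pi, pi / 4)
  expect_equal(v_mid, w, tolerance = 1e-3)
})

test_that("compensation sensitivity matches the finite-difference solver oracle", {
  R <- 0.0127 * 1.16; z0 <- 0.0127; dzc <- 0.3 * z0
  expect_identical(compensated_sensitivity(R, z0, 0, 4), 0)
  tr <- make_trap("cylindrical_compensated")
  basis <- solve_electrode_basis(tr, c(R / 192, z0 / 192),
                                 roles = "compensation", tol = 1e-9)
  fd <- fit_harmonics(as_averaged_potential(basis$compensation), d = tr$d)
  expect_rel(compensated_sensitivity(R, z0, dzc, 2), 2 * fd$A20n, 0.05)
  expect_rel(compensated_sensitivity(R, z0, dzc, 4), 16 * fd$A40n, 0.05)
  expect_rel(compensated_sensitivity(R, z0, dzc, 6), 32 * fd$A60n, 0.05)
  ## Taylor variant has the same sign and order of magnitude at k = 4
  ty <- compensated_sensitivity(R, z0, dzc, 4, method = "taylor")
  expect_equal(sign(ty), sign(16 * fd$A40n))
  expect_rel(ty, 16 * fd$A40n, 0.25)
})

test_that("full and averaged paracell potentials are mutually consistent", {
  par <- make_trap("paracell")
  cons <- paracell_average_consistency(par, n_r = 11, n_z = 21, n_angles = 128)
  expect_lt(cons$max_rel, 0.01)   # within 1% of the trapping voltage
  expect_lt(cons$max_rel, 1e-10)  # the construction is in fact exact
  ## both forms reach the trapping voltage on the end-cap surface (on axis)
  p <- par$params
  z_cap <- sqrt(p$z0^2 - p$R^2 / 2)
  expect_equal(trapping_potential("paracell_averaged", par, 0, 0, 0.9999 * z_cap),
               p$v_trap, tolerance = 1e-3)
  expect_equal(trapping_potential("paracell_full", par, 0, 0, 0.9999 * z_cap),
               p$v_trap, tolerance = 1e-2)
})

test_that("points outside the cell and unreachable tolerances are rejected", {
  cyl <- make_trap("cylindrical")
  expect_error(trapping_potential("cylindrical", cyl, 0.02, 0, 0), "outside")
  expect_error(trapping_potential("cylindrical", cyl, 0.0126, 0, 0,
                                  trunc = series_truncation(10, 1e-12)),
               "tail bound")
})
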