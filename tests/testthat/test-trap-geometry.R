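test_that("default geometries reproduce the reference dimensions and voltages", {
  cub <- make_trap("cubic")
  expect_identical(cub$params$a, 0.0254)
  expect_identical(cub$params$v_trap, 1)
  expect_equal(vapply(cub$electrodes, `[[`, 0, "voltage"), c(1, 0, 0))

  cyl <- make_trap("cylindrical")
  expect_identical(cyl$params$R, 0.0127)
  expect_identical(cyl$params$z0, 0.0127)
  expect_identical(cyl$params$v_trap, 0.988)
  expect_equal(cyl$d^2, 0.5 * (0.0127^2 + 0.5 * 0.0127^2))

  hyp <- make_trap("hyperbolic")
  expect_equal(hyp$z0, 0.0127 / 1.16)
  expect_identical(hyp$params$v_trap, 0.87)

  oc <- make_trap("open_compensated")
  expect_equal(oc$R, 1.0239 * 0.0127)
  expect_identical(oc$params$v_trap, 1.949)
  expect_identical(oc$params$v_c, 0.3235)

  par <- make_trap("paracell")
  expect_identical(par$params$N, 8)
  expect_identical(par$params$beta, 0.9)
  expect_equal(par$z0, 2 * par$R)
  expect_identical(par$params$v_trap, 3.06)

  cc <- make_trap("cylindrical_compensated")
  expect_equal(cc$R, 0.0127 * 1.16)
  expect_equal(cc$params$dz_c, 0.3 * 0.0127)
})

test_that("invalid kinds and parameters are rejected informatively", {
  expect_error(make_trap("octupole_magic"), "valid kinds.*hyperbolic.*paracell")
  expect_error(make_trap("cubic", list(a = -1)), "positive")
  expect_error(make_trap("paracell", list(N = 1)), "N must be an integer >= 2")
  expect_error(make_trap("cubic", list(nonsense = 2)), "unknown parameter")
})

test_that("geometry serialization round-trips bit-exactly", {
  for (kind in trap_kinds()) {
    tr <- make_trap(kind)
    tr2 <- trap_from_json(trap_to_json(tr))
    expect_identical(tr2$params, tr$params)
    expect_identical(tr2$d, tr$d)
    expect_identical(vapply(tr2$electrodes, `[[`, 0, "voltage"),
                     vapply(tr$electrodes, `[[`, 0, "voltage"))
  }
})

test_that("paracell leaf widths follow the z^2 law", {
  tr <- make_trap("paracell")
  p <- tr$params
  leaf <- tr$electrodes[[3]]$surface
  frac_at <- function(z) {  # sampled just outside the wall radius
    th <- seq(0, 2 * pi, length.out = 20001)[-1]
    r <- 1.0001 * p$R
    mean(leaf(r * cos(th), r * sin(th), rep(z, length(th))))
  }
  ## grounded fraction at mid-plane is beta; it collapses to zero at the ends
  expect_equal(frac_at(0), p$beta, tolerance = 1e-3)
  expect_equal(frac_at(0.5 * p$z0), p$beta * (1 - 0.25), tolerance = 1e-3)
  expect_lt(frac_at(0.999 * p$z0), 0.01)
  ## grounded / biased width ratio at z = 0 equals beta / (1 - beta)
  expect_equal(frac_at(0) / (1 - frac_at(0)), p$beta / (1 - p$beta),
               tolerance = 1e-2)
})

test_that("rasterization is mirror-symmetric and covers every electrode", {
  for (kind in c("cylindrical", "hyperbolic_compensated", "open_compensated")) {
    tr <- make_trap(kind)
    bg <- rasterize(tr, min(tr$R, tr$z0) / 24)
    expect_identical(bg$mask, bg$mask[, rev(seq_len(ncol(bg$mask)))])
    expect_identical(bg$value, bg$value[, rev(seq_len(ncol(bg$value)))])
    for (k in seq_along(tr$electrodes)) expect_true(any(bg$mask == k))
  }
  ## cubic: faces are Dirichlet, interior unmasked
  cub <- make_trap("cubic")
  bg <- rasterize(cub, cub$params$a / 32)
  d <- dim(bg$mask)
  expect_true(all(bg$mask[c(1, d[1]), , ] > 0))
  expect_true(all(bg$mask[, , c(1, d[3])] > 0))
  expect_identical(bg$mask[(d[1] + 1) / 2, (d[2] + 1) / 2, (d[3] + 1) / 2], 0L)
  ## trapping plates carry v_trap
  expect_equal(unique(as.vector(bg$value[, , 1])), 1)
})

test_that("rasterization rejects bad spacing and overlapping electrodes", {
  tr <- make_trap("cylindrical")
  expect_error(rasterize(tr, tr$R / 8), "spacing")
  bad <- tr
  bad$electrodes[[3]] <- bad$electrodes[[1]]  # duplicate end-cap solid
  expect_error(rasterize(bad, tr$R / 24), "overlap")
})

test_that("uniform length scaling leaves dimensionless coefficients unchanged", {
  s <- 2.5
  base <- evaluate_trap("cylindrical")
  scaled <- evaluate_trap("cylindrical",
                          config = list(trap_params = list(R = 0.0127 * s,
                                                           z0 = 0.0127 * s),
                                        fit = list(rho_max = 0.010 * s,
                                                   z_max = 0.010 * s)))
  expect_rel(scaled$A20n, base$A20n, 1e-6)
  expect_rel(scaled$A40n, base$A40n, 1e-6)
  expect_rel(scaled$A60n, base$A60n, 1e-6)
})
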