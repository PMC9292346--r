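## Even-order basis of the azimuthally averaged potential:
## phi(rho, z) ~ C + A20 (z^2 - rho^2/2) + A40 (8z^4 - 24z^2rho^2 + 3rho^4)
##                 + A60 (16z^6 - 120z^4rho^2 + 90z^2rho^4 - 5rho^6)
.harm_basis <- function(rho, z) {
  cbind(1,
        z^2 - rho^2 / 2,
        8 * z^4 - 24 * z^2 * rho^2 + 3 * rho^4,
        16 * z^6 - 120 * z^4 * rho^2 + 90 * z^2 * rho^4 - 5 * rho^6)
}

.default_fit_axes <- function(rho_max = 0.010, z_max = 0.010,
                              n_rho = 41, n_z = 81) {
  list(rho = seq(0, rho_max, length.out = n_rho),
       z = seq(-z_max, z_max, length.out = n_z))
}

#' Averaged-potential container
#'
#' @param rho_axis,z_axis Coordinate vectors (m).
#' @param phi_bar Matrix `length(rho_axis) x length(z_axis)` of azimuthally
#'   averaged potential (V).
#' @param valid Logical matrix marking nodes usable for fitting (e.g. nodes
#'   whose sampling circle stayed clear of electrodes).
#' @param source Character tag (`"analytic"`, `"numeric"`, `"synthetic"`).
#' @return Object of class `averaged_potential`.
#' @export
averaged_potential <- function(rho_axis, z_axis, phi_bar, valid = NULL,
                               source = "unknown") {
  stopifnot(nrow(phi_bar) == length(rho_axis), ncol(phi_bar) == length(z_axis))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(phi_bar), ncol(phi_bar))
  structure(list(rho = rho_axis, z = z_axis, phi_bar = phi_bar,
                 valid = valid, source = source),
            class = "averaged_potential")
}

#' Treat an axisymmetric solution as its own azimuthal average
#'
#' For axisymmetric fields, averaging over the polar angle is the identity,
#' so the 2-D solver output is reused directly. Electrode nodes are marked
#' invalid for fitting.
#'
#' @param grid An axisymmetric `potential_grid`.
#' @return An `averaged_potential`.
#' @export
as_averaged_potential <- function(grid) {
  stopifnot(inherits(grid, "potential_grid"))
  if (grid$type != "axisymmetric") {
    stop("use azimuthal_average() for 3-D grids")
  }
  averaged_potential(grid$axes$rho, grid$axes$z, grid$phi,
                     valid = grid$mask == 0L, source = "numeric")
}

.interp2 <- function(xax, zax, arr, px, pz) {
  hx <- xax[2] - xax[1]; hz <- zax[2] - zax[1]
  ix <- pmin(pmax(floor((px - xax[1]) / hx) + 1, 1), length(xax) - 1)
  iz <- pmin(pmax(floor((pz - zax[1]) / hz) + 1, 1), length(zax) - 1)
  tx <- (px - xax[ix]) / hx; tz <- (pz - zax[iz]) / hz
  (1 - tz) * ((1 - tx) * arr[cbind(ix, iz)] + tx * arr[cbind(ix + 1, iz)]) +
    tz * ((1 - tx) * arr[cbind(ix, iz + 1)] + tx * arr[cbind(ix + 1, iz + 1)])
}

.interp3 <- function(axes, arr, px, py, pz) {
  x <- axes$x; y <- axes$y; z <- axes$z
  hx <- x[2] - x[1]; hy <- y[2] - y[1]; hz <- z[2] - z[1]
  ix <- pmin(pmax(floor((px - x[1]) / hx) + 1, 1), length(x) - 1)
  iy <- pmin(pmax(floor((py - y[1]) / hy) + 1, 1), length(y) - 1)
  iz <- pmin(pmax(floor((pz - z[1]) / hz) + 1, 1), length(z) - 1)
  tx <- (px - x[ix]) / hx; ty <- (py - y[iy]) / hy; tz <- (pz - z[iz]) / hz
  g <- function(a, b, c) arr[cbind(a, b, c)]
  (1 - tz) * ((1 - ty) * ((1 - tx) * g(ix, iy, iz) + tx * g(ix + 1, iy, iz)) +
              ty * ((1 - tx) * g(ix, iy + 1, iz) + tx * g(ix + 1, iy + 1, iz))) +
    tz * ((1 - ty) * ((1 - tx) * g(ix, iy, iz + 1) + tx * g(ix + 1, iy, iz + 1)) +
          ty * ((1 - tx) * g(ix, iy + 1, iz + 1) + tx * g(ix + 1, iy + 1, iz + 1)))
}

#' Azimuthal average of a 3-D potential grid
#'
#' Averages a Cartesian 3-D solution over the polar angle by trapezoidal
#' quadrature (exact for a periodic integrand sampled uniformly) with
#' trilinear interpolation. Nodes whose sampling circle intersects an
#' electrode are marked invalid and excluded from later fits.
#'
#' @param field A 3-D `potential_grid` (must have converged).
#' @param n_angles Number of quadrature angles (>= 64).
#' @param rho_axis,z_axis Target axes; default 41 x 81 lattice over 10 mm.
#' @return An `averaged_potential`.
#' @export
azimuthal_average <- function(field, n_angles = 256, rho_axis = NULL,
                              z_axis = NULL) {
  stopifnot(inherits(field, "potential_grid"))
  if (field$type != "cartesian3d") {
    return(as_averaged_potential(field))
  }
  if (n_angles < 64) stop("n_angles must be >= 64")
  if (!isTRUE(field$converged)) stop("field has not converged; refusing to average")
  if (is.null(rho_axis) || is.null(z_axis)) {
    ax <- .default_fit_axes()
    if (is.null(rho_axis)) rho_axis <- ax$rho
    if (is.null(z_axis)) z_axis <- ax$z
  }
  th <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  ct <- cos(th); st <- sin(th)
  nr <- length(rho_axis); nz <- length(z_axis)
  phi_bar <- matrix(NA_real_, nr, nz)
  valid <- matrix(TRUE, nr, nz)
  maskd <- field$mask
  for (i in seq_len(nr)) {
    px <- rho_axis[i] * ct; py <- rho_axis[i] * st
    for (j in seq_len(nz)) {
      pz <- rep(z_axis[j], n_angles)
      vals <- .interp3(field$axes, field$phi, px, py, pz)
      ms <- .interp3(field$axes, maskd + 0, px, py, pz)
      if (any(ms > 0)) valid[i, j] <- FALSE
      phi_bar[i, j] <- mean(vals)
    }
  }
  averaged_potential(rho_axis, z_axis, phi_bar, valid, source = "numeric")
}

#' Least-squares harmonic decomposition of an averaged potential
#'
#' Ordinary least squares of the averaged potential on the basis
#' `{1, z^2 - rho^2/2, 8z^4 - 24z^2 rho^2 + 3 rho^4,
#'   16z^6 - 120z^4 rho^2 + 90z^2 rho^4 - 5 rho^6}` over the rectangular
#' region `rho <= rho_max`, `|z| <= z_max` (10 mm by default). Returns both
#' dimensional coefficients (V/m^2, V/m^4, V/m^6) and dimensionless ones
#' normalized by the length `d`: `A20n = A20 d^2`, `A40n = A40 d^4`,
#' `A60n = A60 d^6`.
#'
#' @param avg An `averaged_potential`.
#' @param d Normalization length (m), `d^2 = (z0^2 + rho0^2/2)/2`.
#' @param rho_max,z_max Fit-region bounds (m).
#' @return Object of class `harmonic_fit`.
#' @export
fit_harmonics <- function(avg, d, rho_max = 0.010, z_max = 0.010) {
  stopifnot(inherits(avg, "averaged_potential"), d > 0)
  if (rho_max > max(avg$rho) + 1e-12 || z_max > max(avg$z) + 1e-12) {
    stop("fit region extends beyond the averaged grid")
  }
  sel_r <- avg$rho <= rho_max + 1e-15
  sel_z <- abs(avg$z) <= z_max + 1e-15
  rho <- avg$rho[sel_r]; z <- avg$z[sel_z]
  phi <- avg$phi_bar[sel_r, sel_z, drop = FALSE]
  ok <- avg$valid[sel_r, sel_z, drop = FALSE] & is.finite(phi)
  pr <- rep(rho, times = length(z))[as.vector(ok)]
  pz <- rep(z, each = length(rho))[as.vector(ok)]
  pphi <- phi[ok]
  if (length(pphi) < 100) stop("fewer than 100 sample nodes in the fit region")
  X <- .harm_basis(pr, pz)
  qrX <- qr(X)
  if (qrX$rank < 4) stop("rank-deficient design: fit region is degenerate")
  cf <- qr.coef(qrX, pphi)
  resid <- pphi - X %*% cf
  structure(list(
    C = cf[1], A20 = cf[2], A40 = cf[3], A60 = cf[4], d = d,
    A20n = cf[2] * d^2, A40n = cf[3] * d^4, A60n = cf[4] * d^6,
    rms_residual = sqrt(mean(resid^2)),
    n_points = length(pphi),
    fit_region = c(rho_max = rho_max, z_max = z_max),
    source = avg$source
  ), class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("harmonic fit (%s): C=%.4g V, A20n=%.3e, A40n=%.3e, A60n=%.3e (d=%.4g m, rms %.2e V, n=%d)\n",
              x$source, x$C, x$A20n, x$A40n, x$A60n, x$d, x$rms_residual,
              x$n_points))
  invisible(x)
}

#' Reconstruct the fitted potential
#'
#' @param fit A `harmonic_fit`.
#' @param rho,z Coordinates (m), vectorized.
#' @return Potential in volts.
#' @export
predict_harmonics <- function(fit, rho, z) {
  n <- max(length(rho), length(z))
  rho <- rep_len(rho, n); z <- rep_len(z, n)
  drop(.harm_basis(rho, z) %*% c(fit$C, fit$A20, fit$A40, fit$A60))
}

#' Synthetic averaged potential with prescribed harmonic content
#'
#' Builds an `averaged_potential` exactly equal to the even-order model with
#' given coefficients; used as a test fixture (exact coefficient recovery,
#' scaling laws, comet-time checks on constructed frequency spreads).
#'
#' @param C Constant (V).
#' @param A20,A40,A60 Dimensional coefficients (V/m^2, V/m^4, V/m^6).
#' @param rho_axis,z_axis Lattice axes; default 41 x 81 over 10 mm.
#' @return An `averaged_potential` with `source = "synthetic"`.
#' @export
synthetic_harmonic_field <- function(C = 0, A20 = 0, A40 = 0, A60 = 0,
                                     rho_axis = NULL, z_axis = NULL) {
  if (is.null(rho_axis) || is.null(z_axis)) {
    ax <- .default_fit_axes()
    if (is.null(rho_axis)) rho_axis <- ax$rho
    if (is.null(z_axis)) z_axis <- ax$z
  }
  pr <- rep(rho_axis, times = length(z_axis))
  pz <- rep(z_axis, each = length(rho_axis))
  phi <- matrix(.harm_basis(pr, pz) %*% c(C, A20, A40, A60),
                length(rho_axis), length(z_axis))
  averaged_potential(rho_axis, z_axis, phi, source = "synthetic")
}

#' Calibrate trap voltages to a reference field curvature
#'
#' Rescales every electrode voltage so that the fitted dimensional `A20`
#' matches a reference value (by electrostatic linearity the refit is exact
#' up to solver tolerance). Used to place different designs at the same axial
#' well depth before comparing their dephasing behaviour.
#'
#' @param trap A `trap_geometry`.
#' @param reference_A20 Target dimensional coefficient (V/m^2).
#' @param config Evaluation options, see [evaluate_trap()].
#' @param fit Optional precomputed `harmonic_fit` of `trap` (skips the field
#'   computation).
#' @return The rescaled `trap_geometry`, with the scale factor in
#'   `attr(, "calibration_factor")`.
#' @export
calibrate_voltage <- function(trap, reference_A20, config = list(), fit = NULL) {
  stopifnot(inherits(trap, "trap_geometry"))
  if (is.null(fit)) {
    cfg <- config
    cfg$trap_params <- trap$params
    a20 <- evaluate_trap(trap, config = cfg)$A20_Vm2
  } else {
    a20 <- fit$A20
  }
  if (!is.finite(a20) || abs(a20) < .Machine$double.eps * 100) {
    stop("fitted A20 is zero; cannot calibrate voltages")
  }
  fac <- reference_A20 / a20
  out <- scale_trap_voltages(trap, fac)
  attr(out, "calibration_factor") <- fac
  out
}
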