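#' Series truncation control
#'
#' @param max_terms Per-index cap on the number of series terms.
#' @param tol Absolute tail tolerance in volts (per unit driving voltage).
#' @return A list used by the series evaluators.
#' @export
series_truncation <- function(max_terms = 500L, tol = 1e-12) {
  if (max_terms < 1) stop("max_terms must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  list(max_terms = as.integer(max_terms), tol = tol)
}

#' Ideal (harmonic) field parameters
#'
#' The ideal trapping potential `alpha*(z^2 - rho^2/2) + chi` satisfies the
#' Laplace equation identically and decouples the three ion motion modes.
#'
#' @param alpha Quadratic strength (V/m^2).
#' @param chi Additive constant (V).
#' @export
ideal_field_params <- function(alpha, chi = 0) {
  stopifnot(is.finite(alpha), is.finite(chi))
  structure(list(alpha = alpha, chi = chi), class = "ideal_field_params")
}

## ---- closed-form potentials ----------------------------------------------

## Rectangular box, trapping plates at z = +-c/2 held at vt, other plates v0.
## Fourier series in cos((2m+1)pi x/a) cos((2n+1)pi y/b) cosh(nu z).
.pot_cuboid <- function(x, y, z, a, b, cc, vt, v0 = 0, trunc = series_truncation()) {
  s <- numeric(length(x))
  gap <- cc / 2 - max(abs(z))  # distance of the farthest point from the plates
  done <- FALSE
  last_bound <- Inf
  for (m in 0:(trunc$max_terms - 1)) {
    lam <- (2 * m + 1) * pi / a
    nu0 <- sqrt(lam^2 + (pi / b)^2)
    last_bound <- 16 / pi^2 / (2 * m + 1) * exp(-nu0 * gap)
    if (last_bound < trunc$tol) { done <- TRUE; break }
    for (n in 0:(trunc$max_terms - 1)) {
      mu <- (2 * n + 1) * pi / b
      nu <- sqrt(lam^2 + mu^2)
      coef <- 16 / pi^2 * (-1)^(m + n) / ((2 * m + 1) * (2 * n + 1))
      if (abs(coef) * exp(-nu * gap) < trunc$tol) break
      ## cosh(nu z)/cosh(nu c/2), overflow-safe
      ratio <- (exp(nu * (z - cc / 2)) + exp(-nu * (z + cc / 2))) / (1 + exp(-nu * cc))
      s <- s + coef * cos(lam * x) * cos(mu * y) * ratio
    }
  }
  if (!done) {
    stop("series not converged at requested tolerance; achieved tail bound ",
         format(last_bound))
  }
  v0 + (vt - v0) * s
}

## Closed cylinder, end caps at vt, side wall 0. Modified-Bessel series with
## gamma_k = k*pi/(2*z0) (k odd), which satisfies both boundary conditions.
.pot_cylindrical <- function(rho, z, R, z0, vt, trunc = series_truncation()) {
  s <- numeric(length(rho))
  gap <- R - max(rho)
  for (k in seq(1, 2 * trunc$max_terms, by = 2)) {
    g <- k * pi / (2 * z0)
    ck <- 4 * sin(k * pi / 2) / (pi * k)
    bound <- abs(ck) * exp(-g * gap)
    if (bound < trunc$tol) break
    ratio <- besselI(g * rho, 0, expon.scaled = TRUE) /
      besselI(g * R, 0, expon.scaled = TRUE) * exp(g * (rho - R))
    s <- s + ck * ratio * cos(g * z)
    if (k >= 2 * trunc$max_terms - 1) {
      stop("series not converged at requested tolerance; achieved tail bound ",
           format(bound))
    }
  }
  vt * (1 - s)
}

## Dynamically harmonized cell, azimuthally averaged potential (exact):
## phi0 * [1 - beta (1 - z^2/z0^2) + beta (R^2 - r^2) / (2 z0^2)]
.pot_paracell_avg <- function(rho, z, R, z0, beta, phi0) {
  phi0 * (1 - beta * (1 - z^2 / z0^2) + beta * (R^2 - rho^2) / (2 * z0^2))
}

## Dynamically harmonized cell, full potential: slice-wise harmonic-measure
## solution for the leaf/trapping wall pattern plus the radial parabolic term.
.pot_paracell_full <- function(x, y, z, R, z0, N, beta, phi0) {
  r2 <- x^2 + y^2
  out <- beta * phi0 * (R^2 - r2) / (2 * z0^2)
  hw <- beta * pi / N * pmax(1 - z^2 / z0^2, 0)
  ang <- numeric(length(x))
  for (n in 0:(N - 1)) {
    tha <- 2 * pi * n / N + hw        # trailing edge of leaf n
    thb <- 2 * pi * (n + 1) / N - hw  # leading edge of leaf n+1
    ax <- R * cos(tha) - x; ay <- R * sin(tha) - y
    bx <- R * cos(thb) - x; by <- R * sin(thb) - y
    ## arg((B - P) * conj(A - P)) in (0, 2*pi): angle swept from A to B
    darg <- atan2(by * ax - bx * ay, bx * ax + by * ay)
    darg <- ifelse(darg < 0, darg + 2 * pi, darg)
    ang <- ang + darg / pi - (thb - tha) / (2 * pi)
  }
  out + phi0 * ang
}

.inside_trap <- function(kind, geometry, x, y, z) {
  p <- geometry$params
  switch(kind,
    cuboid = abs(x) < p$a / 2 & abs(y) < p$b / 2 & abs(z) < p$c / 2,
    cubic = abs(x) < p$a / 2 & abs(y) < p$a / 2 & abs(z) < p$a / 2,
    cylindrical = ,
    cylindrical_dipolar = sqrt(x^2 + y^2) < p$R & abs(z) < p$z0,
    cubic_dipolar = abs(x) < p$a / 2 & abs(y) < p$a / 2 & abs(z) < p$a / 2,
    paracell = sqrt(x^2 + y^2) < p$R &
      2 * z^2 - (x^2 + y^2) < 2 * p$z0^2 - p$R^2,
    rep(TRUE, length(x))
  )
}

#' Closed-form trapping potentials
#'
#' Evaluates the analytic trapping-potential solutions: the ideal harmonic
#' field, the rectangular-box Fourier series (cuboid/cubic), the closed
#' cylinder modified-Bessel series, and the dynamically harmonized cell in
#' its azimuthally averaged (exact closed form) and full (harmonic-measure)
#' variants. All are linear in the driving voltage.
#'
#' @param kind One of `"ideal"`, `"cuboid"`, `"cubic"`, `"cylindrical"`,
#'   `"paracell_averaged"`, `"paracell_full"`.
#' @param geometry For `"ideal"`, an [ideal_field_params()]; otherwise the
#'   matching [make_trap()] geometry.
#' @param x,y,z Point coordinates (m), vectorized; points must lie strictly
#'   inside the cell.
#' @param trunc A [series_truncation()].
#' @return Potential in volts.
#' @export
#' @examples
#' tr <- make_trap("cylindrical", list(R = 0.01, z0 = 0.01, v_trap = 1))
#' trapping_potential("cylindrical", tr, 0, 0, 0) # ~0.2787
trapping_potential <- function(kind, geometry, x, y = 0, z = 0,
                               trunc = series_truncation()) {
  kind <- match.arg(kind, c("ideal", "cuboid", "cubic", "cylindrical",
                            "paracell_averaged", "paracell_full"))
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  if (kind == "ideal") {
    stopifnot(inherits(geometry, "ideal_field_params"))
    return(geometry$alpha * (z^2 - (x^2 + y^2) / 2) + geometry$chi)
  }
  stopifnot(inherits(geometry, "trap_geometry"))
  inside_kind <- switch(kind, paracell_averaged = , paracell_full = "paracell", kind)
  expected <- switch(kind, paracell_averaged = , paracell_full = "paracell", kind)
  if (geometry$kind != expected) {
    stop("geometry is a '", geometry$kind, "' trap; expected '", expected, "'")
  }
  if (!all(.inside_trap(inside_kind, geometry, x, y, z))) {
    stop("point outside cell")
  }
  p <- geometry$params
  switch(kind,
    cuboid = .pot_cuboid(x, y, z, p$a, p$b, p$c, p$v_trap, 0, trunc),
    cubic = .pot_cuboid(x, y, z, p$a, p$a, p$a, p$v_trap, 0, trunc),
    cylindrical = .pot_cylindrical(sqrt(x^2 + y^2), z, p$R, p$z0, p$v_trap, trunc),
    paracell_averaged = .pot_paracell_avg(sqrt(x^2 + y^2), z, p$R, p$z0,
                                          p$beta, p$v_trap),
    paracell_full = .pot_paracell_full(x, y, z, p$R, p$z0, p$N, p$beta, p$v_trap)
  )
}

## Cubic cell dipolar excitation: plates x = +-a/2 at +-v_d/2, other plates 0.
.pot_cubic_dipolar <- function(x, y, z, a, vd, trunc = series_truncation()) {
  s <- numeric(length(x))
  gap <- a / 2 - max(abs(x))
  for (m in 0:(trunc$max_terms - 1)) {
    mu <- (2 * m + 1) * pi / a
    nu0 <- sqrt(mu^2 + (pi / a)^2)
    if (8 / pi^2 / (2 * m + 1) * exp(-nu0 * gap) < trunc$tol) break
    for (n in 0:(trunc$max_terms - 1)) {
      lam <- (2 * n + 1) * pi / a
      nu <- sqrt(mu^2 + lam^2)
      coef <- 8 / pi^2 * (-1)^(m + n) / ((2 * m + 1) * (2 * n + 1))
      if (abs(coef) * exp(-nu * gap) < trunc$tol) break
      ## sinh(nu x)/sinh(nu a/2), overflow-safe
      ratio <- (exp(nu * (x - a / 2)) - exp(-nu * (x + a / 2))) / (1 - exp(-nu * a))
      s <- s + coef * ratio * cos(mu * y) * cos(lam * z)
    }
  }
  vd * s
}

## Closed cylinder dipolar excitation: two opposite wall segments of angular
## half-width alpha at +-v_e, end caps grounded. Re-derived boundary-value
## solution (odd azimuthal orders, axial wavenumbers (k - 1/2) pi / z0).
.pot_cyl_dipolar <- function(x, y, z, R, z0, ve, alpha = pi / 4,
                             trunc = series_truncation()) {
  rho <- sqrt(x^2 + y^2); phi <- atan2(y, x)
  s <- numeric(length(x))
  rmax <- max(rho)
  for (m in seq(1, 2 * trunc$max_terms, by = 2)) {
    am <- 4 * sin(m * alpha) / (m * pi)
    if (abs(am) < 1e-300) next
    if ((rmax / R)^m / m < trunc$tol) break
    for (k in 1:trunc$max_terms) {
      g <- (k - 0.5) * pi / z0
      ck <- 2 * (-1)^(k + 1) / ((k - 0.5) * pi)
      bound <- abs(am * ck) * exp(-g * (R - rmax))
      if (bound < trunc$tol) break
      ratio <- besselI(g * rho, m, expon.scaled = TRUE) /
        besselI(g * R, m, expon.scaled = TRUE) * exp(g * (rho - R))
      s <- s + am * ck * ratio * cos(m * phi) * cos(g * z)
    }
  }
  ve * s
}

#' Closed-form excitation (dipolar) potentials
#'
#' Dipolar excitation fields for the cubic and closed cylindrical cells.
#' Both are odd functions of `x` (antisymmetric about the `x = 0` plane).
#'
#' @param kind `"cubic_dipolar"` or `"cylindrical_dipolar"`.
#' @param geometry The matching `trap_geometry` (`cubic` / `cylindrical`).
#' @param x,y,z Coordinates (m), strictly inside the cell.
#' @param v_dipolar Voltage between the two excitation plates (the plates sit
#'   at `+-v_dipolar/2`).
#' @param alpha Angular half-width of the cylindrical excitation segments
#'   (rad); the default pi/4 corresponds to 90-degree electrodes.
#' @param trunc A [series_truncation()].
#' @return Potential in volts.
#' @export
excitation_potential <- function(kind, geometry, x, y = 0, z = 0,
                                 v_dipolar = 1, alpha = pi / 4,
                                 trunc = series_truncation()) {
  kind <- match.arg(kind, c("cubic_dipolar", "cylindrical_dipolar"))
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  stopifnot(inherits(geometry, "trap_geometry"))
  base <- if (kind == "cubic_dipolar") "cubic" else "cylindrical"
  if (geometry$kind != base) {
    stop("geometry is a '", geometry$kind, "' trap; expected '", base, "'")
  }
  if (!all(.inside_trap(kind, geometry, x, y, z))) stop("point outside cell")
  p <- geometry$params
  if (kind == "cubic_dipolar") {
    .pot_cubic_dipolar(x, y, z, p$a, v_dipolar, trunc)
  } else {
    .pot_cyl_dipolar(x, y, z, p$R, p$z0, v_dipolar / 2, alpha, trunc)
  }
}

#' Near-center expansion of a trapping potential
#'
#' Evaluates the constant and quadratic terms of the near-center expansion
#' `V_trap * [gamma + (alpha_coef / a^2) * (z^2 - rho^2/2)]`, where `a` is the
#' full cell dimension (edge length for the cubic cell, diameter `2R` for the
#' cylindrical cell). `gamma` comes from the exact series at the center;
#' `alpha_coef` from Richardson-extrapolated second differences along `z`.
#'
#' @param kind `"cubic"`, `"cylindrical"` or `"ideal"`.
#' @param geometry Matching geometry ([make_trap()] or [ideal_field_params()]).
#' @param trunc A [series_truncation()].
#' @return List with `gamma`, `alpha_coef` and the reference dimension `a`.
#' @export
center_expansion <- function(kind, geometry, trunc = series_truncation()) {
  kind <- match.arg(kind, c("cubic", "cylindrical", "ideal"))
  if (kind == "ideal") {
    return(list(gamma = geometry$chi, alpha_coef = geometry$alpha, a = 1))
  }
  p <- geometry$params
  a <- if (kind == "cubic") p$a else 2 * p$R
  vt <- p$v_trap
  f <- function(zz) trapping_potential(kind, geometry, 0, 0, zz, trunc)
  gamma <- f(0) / vt
  h <- a / 100
  d2 <- function(h) (f(h) - 2 * f(0) + f(-h)) / h^2
  phi_zz <- (4 * d2(h / 2) - d2(h)) / 3
  list(gamma = gamma, alpha_coef = phi_zz / 2 * a^2 / vt, a = a)
}

#' Compensation-voltage sensitivity of the harmonic coefficients
#'
#' Closed-form sensitivity `V0 * dA_k/dV_c` for a closed compensated
#' cylindrical cell (radius `R`, half-length `z0`) whose compensation bands
#' of axial length `dz_c` sit on the side wall adjacent to the end caps.
#' `A_k` follows the dimensionless convention
#' `phi = (V0/2) * sum_k A_k (r/d)^k P_k(cos theta)` with
#' `d^2 = (z0^2 + R^2/2)/2`. Derived from the boundary-value expansion in
#' `cos(k_n z) I0(k_n rho)` with `k_n = (n + 1/2) pi / z0`.
#'
#' @param R Cylinder radius (m).
#' @param z0 Half-length (m).
#' @param dz_c Compensation electrode length (m), `0 < dz_c < 2*z0`.
#' @param k Even harmonic order (2, 4 or 6 for `"fit"`; any even for
#'   `"taylor"`).
#' @param method `"fit"` (default): the modal solution is sampled on the
#'   standard fit lattice and decomposed by least squares, matching the
#'   convention used for trap evaluation (and the finite-difference solver
#'   oracle). `"taylor"`: the exact Taylor coefficient of the series at the
#'   centre (differs from the fitted value because the fit region is finite).
#' @param fit_region `c(rho_max, z_max)` for `method = "fit"` (m).
#' @param trunc A [series_truncation()].
#' @return Dimensionless sensitivity (a bare number).
#' @export
compensated_sensitivity <- function(R, z0, dz_c, k,
                                    method = c("fit", "taylor"),
                                    fit_region = c(0.010, 0.010),
                                    trunc = series_truncation()) {
  method <- match.arg(method)
  if (k < 2 || k %% 2 != 0) stop("k must be even and >= 2")
  if (dz_c < 0 || dz_c >= 2 * z0) stop("dz_c must be in [0, 2*z0)")
  if (dz_c == 0) return(0)
  d <- sqrt(0.5 * (z0^2 + 0.5 * R^2))
  if (method == "taylor") {
    s <- 0
    for (n in 0:(trunc$max_terms - 1)) {
      kn <- (n + 0.5) * pi / z0
      i0 <- besselI(kn * R, 0, expon.scaled = TRUE) * exp(kn * R)
      term <- 4 * (-1)^n * sin(kn * dz_c / 2)^2 * kn^(k - 1) / (z0 * i0)
      s <- s + term
      if (abs(term) < trunc$tol * max(abs(s), 1e-300) && n > 2) break
      if (n == trunc$max_terms - 1) {
        stop("series not converged at requested tolerance; achieved tail bound ",
             format(abs(term)))
      }
    }
    return(2 * d^k * (-1)^(k / 2) / factorial(k) * s)
  }
  if (!(k %in% c(2, 4, 6))) stop("method = 'fit' supports k in {2, 4, 6}")
  ax <- .default_fit_axes(fit_region[1], fit_region[2])
  phi <- .pot_comp_bands(ax$rho, ax$z, R, z0, dz_c, trunc)
  fit <- fit_harmonics(averaged_potential(ax$rho, ax$z, phi,
                                          source = "analytic"), d = d,
                       rho_max = fit_region[1], z_max = fit_region[2])
  switch(as.character(k),
         "2" = 2 * fit$A20n, "4" = 16 * fit$A40n, "6" = 32 * fit$A60n)
}

## Modal potential of the compensation bands (unit voltage) in a closed
## cylinder: bands of length dz_c on the side wall adjacent to each end cap,
## end caps and the rest of the wall grounded.
.pot_comp_bands <- function(rho_axis, z_axis, R, z0, dz_c,
                            trunc = series_truncation()) {
  out <- matrix(0, length(rho_axis), length(z_axis))
  gap <- R - max(rho_axis)
  for (n in 0:(trunc$max_terms - 1)) {
    kn <- (n + 0.5) * pi / z0
    cn <- 4 * (-1)^n * sin(kn * dz_c / 2)^2 / (z0 * kn)
    if (abs(cn) * exp(-kn * gap) < trunc$tol && n > 2) break
    radial <- besselI(kn * rho_axis, 0, expon.scaled = TRUE) /
      besselI(kn * R, 0, expon.scaled = TRUE) * exp(kn * (rho_axis - R))
    out <- out + cn * outer(radial, cos(kn * z_axis))
  }
  out
}

#' Consistency of the full and averaged paracell potentials
#'
#' Numerically azimuthally averages the full (harmonic-measure) paracell
#' potential and compares it with the closed-form averaged solution over a
#' test grid. Used to validate the reconstruction of both closed forms.
#'
#' @param geometry A `paracell` trap geometry.
#' @param trunc Unused placeholder for interface symmetry.
#' @param n_r,n_z Test-grid size.
#' @param n_angles Quadrature points per circle.
#' @param r_frac,z_frac Fractions of `R` and `z0` covered by the test grid.
#' @return List with `max_abs` (V), `max_rel` (fraction of the trapping
#'   voltage), and the discrepancy matrix with its axes.
#' @export
paracell_average_consistency <- function(geometry, trunc = series_truncation(),
                                         n_r = 21, n_z = 41, n_angles = 256,
                                         r_frac = 0.8, z_frac = 0.8) {
  stopifnot(inherits(geometry, "trap_geometry"), geometry$kind == "paracell")
  p <- geometry$params
  r <- seq(0, r_frac * p$R, length.out = n_r)
  z <- seq(-z_frac * p$z0, z_frac * p$z0, length.out = n_z)
  th <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  disc <- matrix(0, n_r, n_z)
  for (i in seq_len(n_r)) {
    xs <- r[i] * cos(th); ys <- r[i] * sin(th)
    for (j in seq_len(n_z)) {
      full_avg <- mean(.pot_paracell_full(xs, ys, rep(z[j], n_angles),
                                          p$R, p$z0, p$N, p$beta, p$v_trap))
      disc[i, j] <- full_avg - .pot_paracell_avg(r[i], z[j], p$R, p$z0,
                                                 p$beta, p$v_trap)
    }
  }
  list(max_abs = max(abs(disc)), max_rel = max(abs(disc)) / p$v_trap,
       rho = r, z = z, discrepancy = disc)
}
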