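#' Ion and ion-cloud parameters
#'
#' Defaults are the reference simulation conditions: B = 7 T, m/z = 500,
#' cloud radius 2 mm, excitation radius 6 mm and axial half-length
#' 8 mm (= 4 x cloud radius).
#'
#' @param m_over_z Mass-to-charge ratio (Da per elementary charge).
#' @param charge_number Number of elementary charges (integer >= 1).
#' @param B Magnetic field (T).
#' @param r_cloud Ion-cloud radius (m).
#' @param r_excitation Post-excitation cyclotron radius of the cloud centre (m).
#' @param z_cloud Axial half-length of the cloud (m).
#' @return Object of class `ion_cloud_spec` with derived `q` (C) and `m` (kg).
#' @export
ion_cloud_spec <- function(m_over_z = 500, charge_number = 1L, B = 7,
                           r_cloud = 0.002, r_excitation = 0.006,
                           z_cloud = 0.008) {
  if (charge_number < 1 || charge_number != round(charge_number)) {
    stop("charge_number must be an integer >= 1")
  }
  if (m_over_z <= 0) stop("m_over_z must be positive")
  if (r_excitation - r_cloud < 0) stop("r_excitation must be >= r_cloud")
  structure(list(
    m_over_z = m_over_z, charge_number = as.integer(charge_number), B = B,
    r_cloud = r_cloud, r_excitation = r_excitation, z_cloud = z_cloud,
    q = charge_number * .const$e,
    m = m_over_z * charge_number * .const$u
  ), class = "ion_cloud_spec")
}

#' Pure cyclotron frequency
#'
#' `omega_c = q B / m`: the rotation frequency of an ion in a homogeneous
#' magnetic field with no electric field; independent of orbit radius and
#' ion energy.
#'
#' @param spec An [ion_cloud_spec()].
#' @return Angular frequency (rad/s).
#' @export
cyclotron_frequency <- function(spec) {
  stopifnot(inherits(spec, "ion_cloud_spec"))
  spec$q * spec$B / spec$m
}

#' Eigenfrequencies in a quadratic trapping field
#'
#' For an ideal trapping potential with quadratic strength `A20` (V/m^2):
#' `omega_z = sqrt(2 q A20 / m)` and
#' `omega_+- = omega_c/2 +- sqrt((omega_c/2)^2 - q A20 / m)`.
#' The identities `2 omega_+ omega_- = omega_z^2` and
#' `omega_c^2 = omega_+^2 + omega_-^2 + omega_z^2` hold exactly.
#'
#' @param A20 Quadratic coefficient of the trapping potential (V/m^2).
#' @param spec An [ion_cloud_spec()].
#' @return List of class `frequency_set`: `omega_c`, `omega_plus`,
#'   `omega_minus`, `omega_z` (rad/s).
#' @export
eigenfrequencies <- function(A20, spec) {
  wc <- cyclotron_frequency(spec)
  qm <- spec$q / spec$m
  disc <- (wc / 2)^2 - qm * A20
  if (disc < 0) {
    stop("unstable radial motion: A20 exceeds the critical value ",
         format((wc / 2)^2 / qm), " V/m^2")
  }
  root <- sqrt(disc)
  omega_plus <- wc / 2 + root
  ## omega_minus = wc/2 - root suffers catastrophic cancellation for shallow
  ## wells; the algebraically identical quotient form is exact to rounding
  omega_minus <- qm * A20 / omega_plus
  structure(list(
    omega_c = wc,
    omega_plus = omega_plus,
    omega_minus = omega_minus,
    omega_z = sqrt(2 * qm * max(A20, 0))
  ), class = "frequency_set")
}

#' Position-dependent reduced cyclotron frequency
#'
#' Evaluates the local reduced cyclotron frequency from the radial electric
#' field of the even-order harmonic model:
#' `omega_+(rho, z) = omega_c/2 + sqrt((omega_c/2)^2 - (q/m) G(rho, z))` with
#' `G = A20 + A40 (48 z^2 - 12 rho^2) + A60 (240 z^4 - 360 z^2 rho^2 + 30 rho^4)`.
#' Reduces to [eigenfrequencies()] when `A40 = A60 = 0`. The "+" branch is
#' always taken; the magnetron branch is available from [eigenfrequencies()].
#'
#' @param fit A `harmonic_fit` (dimensional coefficients are used).
#' @param rho,z Coordinates (m), vectorized.
#' @param spec An [ion_cloud_spec()].
#' @return `omega_plus` (rad/s), same length as the inputs.
#' @export
local_reduced_frequency <- function(fit, rho, z, spec) {
  stopifnot(inherits(fit, "harmonic_fit"))
  n <- max(length(rho), length(z))
  rho <- rep_len(rho, n); z <- rep_len(z, n)
  wc <- cyclotron_frequency(spec)
  qm <- spec$q / spec$m
  G <- fit$A20 + fit$A40 * (48 * z^2 - 12 * rho^2) +
    fit$A60 * (240 * z^4 - 360 * z^2 * rho^2 + 30 * rho^4)
  disc <- (wc / 2)^2 - qm * G
  if (any(disc < 0)) {
    i <- which(disc < 0)[1]
    stop(sprintf("locally unstable radial motion at (rho, z) = (%g, %g) m",
                 rho[i], z[i]))
  }
  wc / 2 + sqrt(disc)
}

#' Comet-formation (dephasing) time of an ion cloud
#'
#' The cloud loses coherence when the ions with the largest and smallest
#' reduced cyclotron frequency accumulate a polar-angle difference of 2*pi:
#' `T = 2*pi / (max omega_+ - min omega_+)`, with the extrema searched on a
#' dense rectangular grid over the cloud region
#' `rho in [r_excitation - r_cloud, r_excitation + r_cloud]`,
#' `z in [-z_cloud, z_cloud]`.
#'
#' @param fit A `harmonic_fit`.
#' @param spec An [ion_cloud_spec()].
#' @param n_rho,n_z Search-grid size.
#' @return Time in seconds; `Inf` when the frequency spread is below
#'   `1e-12` of the mean (ideal field).
#' @export
comet_time <- function(fit, spec = ion_cloud_spec(), n_rho = 121, n_z = 161) {
  rho <- seq(spec$r_excitation - spec$r_cloud,
             spec$r_excitation + spec$r_cloud, length.out = n_rho)
  z <- seq(-spec$z_cloud, spec$z_cloud, length.out = n_z)
  wp <- local_reduced_frequency(fit,
                                rep(rho, times = n_z),
                                rep(z, each = n_rho), spec)
  spread <- max(wp) - min(wp)
  if (spread < 1e-12 * mean(wp)) return(Inf)
  2 * pi / spread
}

## Build a compensated trap of the given family at aspect ratio R/z0.
.comp_family_trap <- function(family, ratio) {
  switch(family,
    hyperbolic_compensated = make_trap("hyperbolic_compensated",
                                       list(z0 = 0.0127 / ratio)),
    cylindrical_compensated = make_trap("cylindrical_compensated",
                                        list(R = ratio * 0.0127)),
    open_compensated = make_trap("open_compensated", list(R_factor = ratio)),
    stop("unknown compensated family '", family, "'")
  )
}

#' Orthogonalization quality factor of a compensated trap
#'
#' The quality factor `gamma = (V0 dA2/dVc) / (V0 dA4/dVc)` measures how much
#' the compensation voltage shifts the quadratic coefficient relative to the
#' fourth-order one (in the dimensionless Legendre convention normalized by
#' `d`). A trap is orthogonalized when `gamma = 0`: the compensation voltage
#' then tunes `A40` without detuning the reduced cyclotron frequency. The
#' derivatives are exact in `Vc` by superposition: a single solve with the
#' compensation electrodes at 1 V and everything else grounded.
#'
#' @param family `"hyperbolic_compensated"`, `"cylindrical_compensated"` or
#'   `"open_compensated"`.
#' @param ratio Aspect ratio `R/z0`.
#' @param spacing Grid step for the solve (default `R/128`).
#' @param tol,max_iter,omega Solver options, see [solve_laplace()].
#' @param fit_region `c(rho_max, z_max)` in metres.
#' @return `gamma` (dimensionless), with attributes `dA2` and `dA4`.
#' @export
orthogonality_gamma <- function(family, ratio, spacing = NULL,
                                tol = 1e-9, max_iter = 50000L, omega = 1.9,
                                fit_region = c(0.010, 0.010)) {
  trap <- .comp_family_trap(family, ratio)
  if (is.null(spacing)) spacing <- trap$R / 128
  basis <- solve_electrode_basis(trap, spacing, roles = "compensation",
                                 tol = tol, max_iter = max_iter, omega = omega)
  fit <- fit_harmonics(as_averaged_potential(basis$compensation), d = trap$d,
                       rho_max = fit_region[1], z_max = fit_region[2])
  ## Legendre convention: A2 = 2*A20n/V0, A4 = 16*A40n/V0 (per unit Vc)
  dA2 <- 2 * fit$A20n
  dA4 <- 16 * fit$A40n
  if (abs(dA4) < 1e-12 * max(abs(dA2), 1e-300)) {
    warning("dA4/dVc is ~0: gamma is degenerate for this geometry")
  }
  structure(dA2 / dA4, dA2 = dA2, dA4 = dA4)
}

#' Aspect ratio at which a compensated trap becomes orthogonalized
#'
#' Bisects the sign change of [orthogonality_gamma()] over a bracket of
#' aspect ratios `R/z0`.
#'
#' @param family See [orthogonality_gamma()].
#' @param bracket Length-2 numeric bracket (either order).
#' @param rel_tol Relative bracket width at which to stop.
#' @param ... Passed to [orthogonality_gamma()].
#' @return The root `R/z0`, with attribute `n_evals`.
#' @export
find_orthogonal_ratio <- function(family, bracket = c(0.8, 1.5),
                                  rel_tol = 1e-3, ...) {
  lo <- min(bracket); hi <- max(bracket)
  f_lo <- as.numeric(orthogonality_gamma(family, lo, ...))
  f_hi <- as.numeric(orthogonality_gamma(family, hi, ...))
  n <- 2L
  if (sign(f_lo) == sign(f_hi)) {
    stop("gamma does not change sign on [", lo, ", ", hi, "]: no root bracketed")
  }
  while ((hi - lo) > rel_tol * (hi + lo) / 2) {
    mid <- (lo + hi) / 2
    f_mid <- as.numeric(orthogonality_gamma(family, mid, ...))
    n <- n + 1L
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else { hi <- mid }
  }
  structure((lo + hi) / 2, n_evals = n)
}
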