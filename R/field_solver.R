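#' Solve the Dirichlet-Laplace problem on a boundary grid
#'
#' Finite-difference Laplace solver (red-black successive over-relaxation)
#' for axisymmetric `(rho, z)` and Cartesian 3-D grids. The axisymmetric
#' stencil includes the `1/rho` term, with the `rho = 0` axis handled by
#' symmetry. Dirichlet nodes keep their voltages exactly; the discrete
#' maximum principle therefore holds for every converged solution.
#'
#' @param boundary A [boundary_grid()]. The grid boundary must be closed
#'   (every edge node Dirichlet, except the symmetry axis).
#' @param tol Residual target in volts: the maximum absolute Gauss-Seidel
#'   displacement per sweep.
#' @param max_iter Maximum number of sweeps.
#' @param omega Over-relaxation factor.
#' @return An object of class `potential_grid`: `axes`, `phi`, `mask`,
#'   `converged`, `residual`, `iterations`.
#' @export
solve_laplace <- function(boundary, tol = 1e-8, max_iter = 50000L, omega = 1.9) {
  stopifnot(inherits(boundary, "boundary_grid"))
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  .check_closed(boundary)
  if (boundary$type == "axisymmetric") {
    hr <- diff(boundary$axes$rho[1:2]); hz <- diff(boundary$axes$z[1:2])
    out <- sor_axisym_cpp(boundary$value, boundary$mask, hr, hz,
                          omega, tol, as.integer(max_iter))
  } else {
    dims <- dim(boundary$mask)
    hx <- diff(boundary$axes$x[1:2]); hy <- diff(boundary$axes$y[1:2])
    hz <- diff(boundary$axes$z[1:2])
    out <- sor_cart3_cpp(as.vector(boundary$value),
                         as.vector(boundary$mask), as.integer(dims),
                         hx, hy, hz, omega, tol, as.integer(max_iter))
  }
  if (isTRUE(out$diverged)) {
    stop("SOR diverged: residual grew over 100 sweeps (residual = ",
         format(out$residual), " V)")
  }
  structure(list(type = boundary$type, axes = boundary$axes,
                 phi = out$phi, mask = boundary$mask,
                 electrodes = boundary$electrodes,
                 trap_kind = boundary$trap_kind,
                 converged = out$converged, residual = out$residual,
                 iterations = out$iterations, tol = tol),
            class = "potential_grid")
}

.check_closed <- function(bg) {
  m <- bg$mask
  if (bg$type == "axisymmetric") {
    d <- dim(m)
    edges <- c(m[d[1], ], m[, 1], m[, d[2]])
  } else {
    d <- dim(m)
    edges <- c(m[c(1, d[1]), , ], m[, c(1, d[2]), ], m[, , c(1, d[3])])
  }
  if (any(edges == 0L)) {
    stop("open boundary: the solution of the Dirichlet problem is not bounded; ",
         "close the outer box (grounded or electrode-covered)")
  }
  invisible(TRUE)
}

#' @export
print.potential_grid <- function(x, ...) {
  cat("potential grid (", x$type, "), ",
      paste(vapply(x$axes, length, 1L), collapse = " x "), " nodes; ",
      if (x$converged) "converged" else "NOT converged",
      " (residual ", format(x$residual, digits = 3), " V, ",
      x$iterations, " sweeps)\n", sep = "")
  invisible(x)
}

#' Linear combination of basis potential grids
#'
#' Per-electrode unit-voltage solutions can be recombined linearly
#' (superposition), which makes voltage scans exact up to solver tolerance.
#'
#' @param solutions List of `potential_grid`s on identical grids.
#' @param weights Numeric vector of multipliers.
#' @return A `potential_grid` whose `phi` is the weighted sum.
#' @export
combine_solutions <- function(solutions, weights) {
  stopifnot(length(solutions) == length(weights), length(solutions) >= 1)
  out <- solutions[[1]]
  phi <- out$phi * weights[1]
  if (length(solutions) > 1) {
    for (i in 2:length(solutions)) phi <- phi + solutions[[i]]$phi * weights[i]
  }
  out$phi <- phi
  out$residual <- sum(abs(weights) * vapply(solutions, `[[`, 1, "residual"))
  out
}

#' Per-electrode unit-voltage basis solutions
#'
#' Solves the Laplace problem once per electrode role with that role's
#' electrodes at 1 V and everything else grounded. The full solution at any
#' voltage setting is then a weighted [combine_solutions()] of the basis.
#'
#' @param trap A `trap_geometry`.
#' @param spacing Grid step passed to [rasterize()].
#' @param roles Roles to energize one at a time.
#' @inheritParams solve_laplace
#' @return Named list of `potential_grid`s.
#' @export
solve_electrode_basis <- function(trap, spacing, roles = c("trapping", "compensation"),
                                  tol = 1e-8, max_iter = 50000L, omega = 1.9) {
  roles <- intersect(roles, unique(vapply(trap$electrodes, `[[`, "", "role")))
  out <- list()
  for (r in roles) {
    zeroed <- stats::setNames(as.list(rep(0, length(.electrode_roles))), .electrode_roles)
    zeroed[[r]] <- 1
    tr <- set_trap_voltages(trap, zeroed)
    out[[r]] <- solve_laplace(rasterize(tr, spacing), tol = tol,
                              max_iter = max_iter, omega = omega)
  }
  out
}

#' Grid-refinement study of the fitted harmonic coefficients
#'
#' Rasterizes and solves a trap at a sequence of grid spacings and reports
#' the fitted coefficients at each spacing together with Richardson-style
#' drift estimates between consecutive levels, for choosing a production
#' spacing.
#'
#' @param trap A `trap_geometry` (axisymmetric designs).
#' @param spacings Numeric vector (>= 3 values, ideally a geometric sequence).
#' @param ... Passed to [solve_laplace()].
#' @param fit_region Fit bounds in metres, see [fit_harmonics()].
#' @return data.frame with one row per spacing: spacing, C, A20n, A40n, A60n,
#'   residual, and drift columns (absolute change from the previous level).
#' @export
refine_study <- function(trap, spacings, fit_region = c(0.010, 0.010), ...) {
  if (length(spacings) < 3) stop("need at least 3 spacings")
  spacings <- sort(spacings, decreasing = TRUE)
  rows <- lapply(spacings, function(h) {
    pg <- solve_laplace(rasterize(trap, h), ...)
    fit <- fit_harmonics(as_averaged_potential(pg), d = trap$d,
                         rho_max = fit_region[1], z_max = fit_region[2])
    data.frame(spacing = h, C = fit$C, A20n = fit$A20n, A40n = fit$A40n,
               A60n = fit$A60n, residual = pg$residual)
  })
  out <- do.call(rbind, rows)
  for (col in c("A20n", "A40n", "A60n")) {
    out[[paste0("drift_", col)]] <- c(NA, abs(diff(out[[col]])))
  }
  out
}

#' Export a potential grid as plain text
#'
#' Writes the grid as a tidy TSV (coordinates, mask, potential), a portable
#' text representation suitable for external plotting tools.
#'
#' @param grid A `potential_grid`.
#' @param path Output file path.
#' @export
write_potential_grid <- function(grid, path) {
  stopifnot(inherits(grid, "potential_grid"))
  if (grid$type == "axisymmetric") {
    df <- expand.grid(rho = grid$axes$rho, z = grid$axes$z)
    df$mask <- as.vector(grid$mask); df$phi <- as.vector(grid$phi)
  } else {
    df <- expand.grid(x = grid$axes$x, y = grid$axes$y, z = grid$axes$z)
    df$mask <- as.vector(grid$mask); df$phi <- as.vector(grid$phi)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
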