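#' Construct a boundary grid directly
#'
#' Low-level constructor for a Dirichlet boundary-value problem on a uniform
#' grid, used by [rasterize()] and available for custom problems (e.g.
#' detection weight fields). Axisymmetric grids are matrices indexed
#' `(rho, z)` with `rho` starting at 0; Cartesian grids are 3-D arrays
#' indexed `(x, y, z)`.
#'
#' @param axes Named list of coordinate vectors: `list(rho=, z=)` or
#'   `list(x=, y=, z=)`. Each must be uniformly spaced.
#' @param mask Integer array, same shape as the grid: 0 for vacuum nodes,
#'   `k > 0` for nodes inside electrode `k`.
#' @param value Numeric array of Dirichlet voltages (ignored where `mask == 0`).
#' @param electrodes Optional list describing the electrodes (label/role/voltage).
#' @return An object of class `boundary_grid`.
#' @export
boundary_grid <- function(axes, mask, value, electrodes = NULL) {
  type <- if (setequal(names(axes), c("rho", "z"))) "axisymmetric" else "cartesian3d"
  if (type == "cartesian3d" && !setequal(names(axes), c("x", "y", "z"))) {
    stop("axes must be named (rho, z) or (x, y, z)")
  }
  for (ax in axes) {
    d <- diff(ax)
    if (length(d) < 2 || max(abs(d - d[1])) > 1e-9 * abs(d[1])) {
      stop("axes must be uniformly spaced")
    }
  }
  if (type == "axisymmetric" && abs(axes$rho[1]) > 1e-15) {
    stop("axisymmetric grids must start at rho = 0")
  }
  dims <- vapply(axes, length, 1L)
  stopifnot(all(dim(mask) == dims), all(dim(value) == dims))
  if (!any(mask > 0)) stop("boundary grid has no Dirichlet nodes")
  structure(list(type = type, axes = axes, mask = mask, value = value,
                 electrodes = electrodes),
            class = "boundary_grid")
}

#' @export
print.boundary_grid <- function(x, ...) {
  dims <- paste(vapply(x$axes, length, 1L), collapse = " x ")
  cat("boundary grid (", x$type, "), ", dims, " nodes, ",
      sum(x$mask > 0), " Dirichlet\n", sep = "")
  invisible(x)
}

.axis_to <- function(extent, spacing) {
  n <- max(1L, round(extent / spacing))
  list(h = extent / n, n = n)
}

#' Rasterize a trap geometry onto a solver grid
#'
#' Samples the electrode solids of a [make_trap()] geometry onto a uniform
#' grid: a 2-D `(rho, z)` grid for axisymmetric designs, a 3-D `(x, y, z)`
#' grid otherwise. Every node inside an electrode becomes a Dirichlet node at
#' that electrode's voltage. Open designs (truncated hyperbolic cells) are
#' closed by a grounded outer box at `box_factor` times the electrode extent;
#' for closed designs the grid boundary coincides with the electrode
#' assembly. Curved surfaces are represented by nearest-node snapping of the
#' implicit inequalities (no sub-cell interpolation).
#'
#' @param trap A `trap_geometry`.
#' @param spacing Target grid step (m): a scalar, or per-axis steps
#'   (`c(rho, z)` for axisymmetric grids, `c(x, y, z)` for 3-D). Must satisfy
#'   `max(spacing) <= min(R, z0)/16`. The step is rounded per axis so that
#'   grid nodes fall exactly on the box boundary; the grid is
#'   mirror-symmetric in `z` to machine exactness.
#' @param box_factor Outer-box factor for open designs (default 1.5).
#' @return A [boundary_grid()].
#' @export
#' @examples
#' bg <- rasterize(make_trap("cylindrical"), spacing = 0.0127 / 32)
#' dim(bg$mask)
rasterize <- function(trap, spacing, box_factor = 1.5) {
  stopifnot(inherits(trap, "trap_geometry"))
  if (!is.numeric(spacing) || any(spacing <= 0)) stop("spacing must be > 0")
  if (max(spacing) > min(trap$R, trap$z0) / 16) {
    stop("spacing must be <= min(R, z0)/16 = ",
         format(min(trap$R, trap$z0) / 16), " m")
  }
  axisym <- identical(trap$symmetry, "axisymmetric")
  if (axisym) {
    spacing <- rep_len(spacing, 2L)
    rho_ext <- trap$extent$rho; z_ext <- trap$extent$z
    if (!trap$closed) { rho_ext <- rho_ext * box_factor; z_ext <- z_ext * box_factor }
    ar <- .axis_to(rho_ext, spacing[1]); az <- .axis_to(z_ext, spacing[2])
    rho <- seq(0L, ar$n) * ar$h
    z <- seq(-az$n, az$n) * az$h
    pts_rho <- rep(rho, times = length(z))
    pts_z <- rep(z, each = length(rho))
    dims <- c(length(rho), length(z))
    mask <- matrix(0L, dims[1], dims[2])
    value <- matrix(0, dims[1], dims[2])
    for (k in seq_along(trap$electrodes)) {
      e <- trap$electrodes[[k]]
      inside <- e$surface(pts_rho, pts_z)
      clash <- inside & mask > 0
      if (any(clash)) {
        other <- trap$electrodes[[mask[which(clash)[1]]]]$label
        stop("electrode overlap: '", e$label,
             "' claims nodes already held by '", other, "'")
      }
      mask[inside] <- k
      value[inside] <- e$voltage
    }
    ## grounded closure for open designs; closed designs must already cover
    edge <- matrix(FALSE, dims[1], dims[2])
    edge[dims[1], ] <- TRUE; edge[, 1] <- TRUE; edge[, dims[2]] <- TRUE
    openedge <- edge & mask == 0L
    if (any(openedge)) {
      if (trap$closed) stop("internal error: closed design leaves open boundary")
      mask[openedge] <- length(trap$electrodes) + 1L
      value[openedge] <- 0
    }
    axes <- list(rho = rho, z = z)
  } else {
    spacing <- rep_len(spacing, 3L)
    ex <- trap$extent
    ax <- .axis_to(ex$x, spacing[1]); ay <- .axis_to(ex$y, spacing[2])
    az <- .axis_to(ex$z, spacing[3])
    x <- seq(-ax$n, ax$n) * ax$h
    y <- seq(-ay$n, ay$n) * ay$h
    z <- seq(-az$n, az$n) * az$h
    dims <- c(length(x), length(y), length(z))
    gx <- rep(x, times = dims[2] * dims[3])
    gy <- rep(rep(y, each = dims[1]), times = dims[3])
    gz <- rep(z, each = dims[1] * dims[2])
    mask <- array(0L, dims)
    value <- array(0, dims)
    for (k in seq_along(trap$electrodes)) {
      e <- trap$electrodes[[k]]
      inside <- e$surface(gx, gy, gz)
      if (any(inside & mask > 0)) {
        stop("electrode overlap: '", e$label, "' claims already-assigned nodes")
      }
      mask[inside] <- k
      value[inside] <- e$voltage
    }
    edge <- array(FALSE, dims)
    edge[c(1, dims[1]), , ] <- TRUE
    edge[, c(1, dims[2]), ] <- TRUE
    edge[, , c(1, dims[3])] <- TRUE
    openedge <- edge & mask == 0L
    if (any(openedge)) {
      if (trap$closed) stop("internal error: closed design leaves open boundary")
      mask[openedge] <- length(trap$electrodes) + 1L
      value[openedge] <- 0
    }
    axes <- list(x = x, y = y, z = z)
  }
  el <- lapply(trap$electrodes, function(e) list(label = e$label, role = e$role,
                                                voltage = e$voltage))
  ## every electrode must be represented at the chosen resolution
  for (k in seq_along(trap$electrodes)) {
    if (!any(mask == k)) {
      stop("electrode '", trap$electrodes[[k]]$label,
           "' contributes no boundary node at spacing ", format(spacing))
    }
  }
  bg <- boundary_grid(axes, mask, value, electrodes = el)
  bg$trap_kind <- trap$kind
  bg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
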