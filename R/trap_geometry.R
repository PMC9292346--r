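#' Supported ICR cell designs
#'
#' @return Character vector with the identifiers of the eleven cell designs
#'   that [make_trap()] can build.
#' @export
trap_kinds <- function() {
  c("hyperbolic", "hyperbolic_compensated", "cuboid", "cubic",
    "cylindrical", "cylindrical_compensated", "open_compensated",
    "tolmachev", "brustkern", "ring_electrode", "paracell")
}

.electrode_roles <- c("trapping", "excitation", "detection", "compensation", "ground")

## An electrode is a labelled solid region (implicit predicate) held at a DC
## voltage. Predicates take (rho, z) for axisymmetric designs and (x, y, z)
## for 3-D designs; they are vectorized and deterministic.
electrode_spec <- function(label, role, voltage, surface) {
  stopifnot(is.character(label), length(label) == 1L)
  role <- match.arg(role, .electrode_roles)
  if (!is.finite(voltage)) stop("electrode voltage must be finite")
  structure(list(label = label, role = role, voltage = voltage,
                 surface = surface),
            class = "electrode_spec")
}

#' Construct an ICR cell geometry
#'
#' Builds one of the eleven classical cell designs as a set of labelled
#' electrode solids with applied DC voltages, plus the characteristic lengths
#' used for normalization. Default parameters are the reference geometries
#' and voltages of the comparative evaluation (all lengths in metres,
#' voltages in volts).
#'
#' The normalization length `d` obeys `d^2 = (z0^2 + rho0^2/2)/2` with
#' per-design characteristic half-lengths `z0` (axial) and `rho0` (radial).
#'
#' @param kind One of [trap_kinds()].
#' @param params Named list of overrides for the design's parameters
#'   (e.g. `R`, `z0`, `v_trap`, `v_c`). Lengths must be positive.
#' @return An object of class `trap_geometry`: a list with `kind`, `params`
#'   (fully resolved), `electrodes`, characteristic lengths `R`, `z0`,
#'   `rho0`, normalization length `d`, `symmetry`
#'   (`"axisymmetric"`, `"mirror_xy_only"` or `"N_fold"`), and the bounding
#'   extents of the electrode assembly.
#' @export
#' @examples
#' tr <- make_trap("cubic")
#' tr$params$a      # 0.0254 m full edge
#' tr$electrodes[[1]]$voltage
make_trap <- function(kind, params = list()) {
  kinds <- trap_kinds()
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop("unknown trap kind ", deparse(kind), "; valid kinds: ",
         paste(kinds, collapse = ", "))
  }
  builder <- switch(kind,
    hyperbolic              = .trap_hyperbolic,
    hyperbolic_compensated  = .trap_hyperbolic_comp,
    cuboid                  = .trap_cuboid,
    cubic                   = .trap_cubic,
    cylindrical             = .trap_cylindrical,
    cylindrical_compensated = .trap_cylindrical_comp,
    open_compensated        = .trap_open_comp,
    tolmachev               = .trap_tolmachev,
    brustkern               = .trap_brustkern,
    ring_electrode          = .trap_ring_electrode,
    paracell                = .trap_paracell
  )
  tr <- builder(params)
  len_names <- intersect(names(tr$params),
                         c("R", "z0", "a", "b", "c", "r_c", "rmax", "dz_c",
                           "z_e", "dz1", "dz2"))
  for (nm in len_names) {
    if (!is.numeric(tr$params[[nm]]) || tr$params[[nm]] <= 0) {
      stop("trap parameter ", nm, " must be positive")
    }
  }
  tr$kind <- kind
  tr$d <- sqrt(0.5 * (tr$z0^2 + 0.5 * tr$rho0^2))
  class(tr) <- "trap_geometry"
  tr
}

#' @export
print.trap_geometry <- function(x, ...) {
  cat("ICR cell geometry:", x$kind, "\n")
  cat(sprintf("  z0 = %.6g m, rho0 = %.6g m, d = %.6g m (%s)\n",
              x$z0, x$rho0, x$d, x$symmetry))
  for (e in x$electrodes) {
    cat(sprintf("  electrode %-28s role=%-12s V=%g\n", e$label, e$role, e$voltage))
  }
  invisible(x)
}

.resolve <- function(defaults, params) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  defaults
}

## ---- closed hyperbolic cells -------------------------------------------

.trap_hyperbolic <- function(params, compensated = FALSE) {
  p <- .resolve(list(R = 0.0127, z0 = 0.0127 / 1.16, rmax_factor = 2,
                     v_trap = 0.87, r_c_factor = 2, v_c = 0.455), params)
  R <- p$R; z0 <- p$z0; rmax <- p$rmax_factor * R
  endcap <- function(rho, z) (2 * z^2 - rho^2 >= 2 * z0^2) & (rho <= rmax)
  ring   <- function(rho, z) (rho^2 - 2 * z^2 >= R^2) & (rho <= rmax)
  el <- list(
    electrode_spec("end caps (hyperbolic)", "trapping", p$v_trap, endcap),
    electrode_spec("ring (split excitation/detection, 0 V DC)", "ground", 0, ring)
  )
  if (compensated) {
    r_c <- p$r_c_factor * R
    comp <- function(rho, z) {
      (sqrt(rho^2 + z^2) >= r_c) &
        (2 * z^2 - rho^2 < 2 * z0^2) & (rho^2 - 2 * z^2 < R^2)
    }
    el <- c(el, list(electrode_spec("compensation arc", "compensation", p$v_c, comp)))
  }
  z_ext <- sqrt(z0^2 + rmax^2 / 2)  # end-cap hyperbola at rho = rmax
  list(params = p, electrodes = el, R = R, z0 = z0, rho0 = R,
       symmetry = "axisymmetric",
       extent = list(rho = rmax, z = z_ext), closed = FALSE)
}

.trap_hyperbolic_comp <- function(params) {
  tr <- .trap_hyperbolic(params, compensated = TRUE)
  tr
}

## ---- rectangular cells --------------------------------------------------

## a, b, c are the full lengths along x, y, z; trapping plates are the pair
## perpendicular to z (the magnetic-field axis).
.trap_box <- function(a, b, cc, v_trap) {
  list(
    electrode_spec("trapping plates (z)", "trapping", v_trap,
                   function(x, y, z) abs(z) >= cc / 2),
    electrode_spec("excitation plates (x)", "excitation", 0,
                   function(x, y, z) (abs(x) >= a / 2) & (abs(z) < cc / 2)),
    electrode_spec("detection plates (y)", "detection", 0,
                   function(x, y, z) (abs(y) >= b / 2) & (abs(x) < a / 2) & (abs(z) < cc / 2))
  )
}

.trap_cuboid <- function(params) {
  p <- .resolve(list(a = 0.0762, b = 0.0254, c = 0.0254, v_trap = 1.2), params)
  list(params = p, electrodes = .trap_box(p$a, p$b, p$c, p$v_trap),
       R = max(p$a, p$b) / 2, z0 = p$c / 2, rho0 = max(p$a, p$b) / 2,
       symmetry = "mirror_xy_only",
       extent = list(x = p$a / 2, y = p$b / 2, z = p$c / 2), closed = TRUE)
}

.trap_cubic <- function(params) {
  p <- .resolve(list(a = 0.0254, v_trap = 1), params)
  list(params = p, electrodes = .trap_box(p$a, p$a, p$a, p$v_trap),
       R = p$a / 2, z0 = p$a / 2, rho0 = p$a / 2,
       symmetry = "mirror_xy_only",
       extent = list(x = p$a / 2, y = p$a / 2, z = p$a / 2), closed = TRUE)
}

## ---- cylindrical cells --------------------------------------------------

.trap_cylindrical <- function(params) {
  p <- .resolve(list(R = 0.0127, z0 = 0.0127, v_trap = 0.988), params)
  R <- p$R; z0 <- p$z0
  el <- list(
    electrode_spec("end caps", "trapping", p$v_trap,
                   function(rho, z) abs(z) >= z0),
    electrode_spec("side (split excitation/detection, 0 V DC)", "ground", 0,
                   function(rho, z) (rho >= R) & (abs(z) < z0))
  )
  list(params = p, electrodes = el, R = R, z0 = z0, rho0 = R,
       symmetry = "axisymmetric", extent = list(rho = R, z = z0), closed = TRUE)
}

.trap_cylindrical_comp <- function(params) {
  p <- .resolve(list(R = 0.0127 * 1.16, z0 = 0.0127, dz_c = 0.3 * 0.0127,
                     v_trap = 1, v_c = 0.145), params)
  R <- p$R; z0 <- p$z0; dz <- p$dz_c
  if (dz >= 2 * z0) stop("compensation electrode length must be < 2*z0")
  el <- list(
    electrode_spec("end caps", "trapping", p$v_trap,
                   function(rho, z) abs(z) >= z0),
    electrode_spec("compensation bands", "compensation", p$v_c,
                   function(rho, z) (rho >= R) & (abs(z) < z0) & (abs(z) >= z0 - dz)),
    electrode_spec("side (split excitation/detection, 0 V DC)", "ground", 0,
                   function(rho, z) (rho >= R) & (abs(z) < z0 - dz))
  )
  list(params = p, electrodes = el, R = R, z0 = z0, rho0 = R,
       symmetry = "axisymmetric", extent = list(rho = R, z = z0), closed = TRUE)
}

## Open cylinder built from stacked wall segments; the wall solid fills
## rho >= R so the simulation box is closed by construction. `segments` is a
## data.frame-like list with z ranges [lo, hi) mirrored across z = 0.
.stacked_cylinder <- function(R, segments) {
  mk <- function(lo, hi) {
    force(lo); force(hi)
    function(rho, z) (rho >= R) & (abs(z) >= lo) & (abs(z) < hi)
  }
  lapply(seq_along(segments$lo), function(i) {
    electrode_spec(segments$label[i], segments$role[i], segments$voltage[i],
                   mk(segments$lo[i], segments$hi[i]))
  })
}

.trap_open_comp <- function(params) {
  p <- .resolve(list(z0 = 0.0127, R_factor = 1.0239, dz_factor = 0.8351,
                     ze_factor = 4.327, v_trap = 1.949, v_c = 0.3235), params)
  z0 <- p$z0; R <- p$R_factor * z0
  dz <- p$dz_factor * z0; ze <- p$ze_factor * z0
  zend <- z0 + ze
  segs <- list(
    lo = c(0, z0 - dz, z0),
    hi = c(z0 - dz, z0, zend),
    label = c("central ring (excitation/detection, 0 V DC)",
              "compensation electrodes", "trapping cylinders"),
    role = c("ground", "compensation", "trapping"),
    voltage = c(0, p$v_c, p$v_trap)
  )
  el <- c(.stacked_cylinder(R, segs),
          list(electrode_spec("grounded end plates", "ground", 0,
                              function(rho, z) abs(z) >= zend)))
  list(params = p, electrodes = el, R = R, z0 = z0, rho0 = R,
       symmetry = "axisymmetric", extent = list(rho = R, z = zend), closed = TRUE)
}

.trap_tolmachev <- function(params) {
  p <- .resolve(list(R = 0.0127, z0_factor = 1.3, dz1_factor = 0.4,
                     dz2_factor = 0.4, ze_factor = 2,
                     v_trap = 2.3, v_c1_frac = 0.1333, v_c2_frac = 0.3167),
                params)
  R <- p$R; z0 <- p$z0_factor * R
  dz1 <- p$dz1_factor * R; dz2 <- p$dz2_factor * R; ze <- p$ze_factor * R
  zend <- z0 + ze
  segs <- list(
    lo = c(0, z0 - dz1 - dz2, z0 - dz2, z0),
    hi = c(z0 - dz1 - dz2, z0 - dz2, z0, zend),
    label = c("central ring (excitation/detection, 0 V DC)",
              "compensation ring 1", "compensation ring 2",
              "trapping cylinders"),
    role = c("ground", "compensation", "compensation", "trapping"),
    voltage = c(0, p$v_c1_frac * p$v_trap, p$v_c2_frac * p$v_trap, p$v_trap)
  )
  el <- c(.stacked_cylinder(R, segs),
          list(electrode_spec("grounded end plates", "ground", 0,
                              function(rho, z) abs(z) >= zend)))
  list(params = p, electrodes = el, R = R, z0 = z0, rho0 = R,
       symmetry = "axisymmetric", extent = list(rho = R, z = zend), closed = TRUE)
}

.trap_brustkern <- function(params) {
  p <- .resolve(list(R = 0.0127, unit_div = 31.24, z_t = 21.87,
                     l_c0 = 1.55, l_c1 = 5.05, l_c2 = 3.05,
                     k = 0.06269, v_trap_k = 35, v_c0_k = 9.608,
                     v_c1_k = 1, v_c2_k = 9.608, outer_factor = 1.5), params)
  R <- p$R; a <- R / p$unit_div
  z_t <- p$z_t * a                        # inner edge of trapping electrodes
  lc <- c(p$l_c0, p$l_c1, p$l_c2) * a     # compensation ring lengths
  z_d <- z_t - sum(lc)                    # central ring half-length
  l_t <- z_t                              # trapping electrode length (assumption)
  l_out <- p$outer_factor * (l_t + sum(lc))
  zend <- z_t + l_t + l_out
  k <- p$k
  segs <- list(
    lo = c(0, z_d, z_d + lc[1], z_d + lc[1] + lc[2], z_t, z_t + l_t),
    hi = c(z_d, z_d + lc[1], z_d + lc[1] + lc[2], z_t, z_t + l_t, zend),
    label = c("central ring (excitation/detection, 0 V DC)",
              "compensation ring 0", "compensation ring 1",
              "compensation ring 2", "trapping cylinders",
              "outer grounded cylinders"),
    role = c("ground", "compensation", "compensation", "compensation",
             "trapping", "ground"),
    voltage = c(0, p$v_c0_k * k, p$v_c1_k * k, p$v_c2_k * k, p$v_trap_k * k, 0)
  )
  el <- c(.stacked_cylinder(R, segs),
          list(electrode_spec("grounded end plates", "ground", 0,
                              function(rho, z) abs(z) >= zend)))
  list(params = p, electrodes = el, R = R, z0 = z_t, rho0 = R,
       symmetry = "axisymmetric", extent = list(rho = R, z = zend), closed = TRUE)
}

.trap_ring_electrode <- function(params) {
  p <- .resolve(list(R = 0.0127, z0 = 0.0127, n_rings = 5,
                     ring_width_raw = 0.11 / 1.875, ring_gap_raw = 0.039 / 1.875,
                     ring_unit = NA_real_,
                     ring_voltages = c(0.2, 1.1, 2.0, 2.4, 2.8),
                     plate_thickness_factor = 0.02, back_factor = 1.3), params)
  R <- p$R; z0 <- p$z0; nr <- p$n_rings
  if (length(p$ring_voltages) != nr) stop("need one voltage per ring")
  ## widths/gaps are given in ambiguous relative units; by default scale them
  ## so that n_rings rings and (n_rings - 1) gaps tile the end-cap radius.
  unit <- p$ring_unit
  if (is.na(unit)) {
    unit <- R / (nr * p$ring_width_raw + (nr - 1) * p$ring_gap_raw)
  }
  w <- p$ring_width_raw * unit; g <- p$ring_gap_raw * unit
  thick <- p$plate_thickness_factor * z0
  lo <- (seq_len(nr) - 1) * (w + g); hi <- lo + w
  mk_ring <- function(l, h) {
    force(l); force(h)
    function(rho, z) (abs(z) >= z0) & (abs(z) < z0 + thick) & (rho >= l) & (rho < h)
  }
  rings <- lapply(seq_len(nr), function(i) {
    electrode_spec(sprintf("trapping ring %d", i), "trapping",
                   p$ring_voltages[i], mk_ring(lo[i], hi[i]))
  })
  zback <- p$back_factor * z0
  el <- c(rings, list(
    electrode_spec("side (excitation/detection, 0 V DC)", "ground", 0,
                   function(rho, z) (rho >= R) & (abs(z) < zback)),
    electrode_spec("grounded back plates", "ground", 0,
                   function(rho, z) abs(z) >= zback)
  ))
  out <- list(params = p, electrodes = el, R = R, z0 = z0, rho0 = R,
              symmetry = "axisymmetric", extent = list(rho = R, z = zback),
              closed = TRUE)
  out$ring_unit_resolved <- unit  # derived, not a serialized parameter
  out
}

## ---- dynamically harmonized cell (paracell) -----------------------------

## Grounded "leaf" electrodes on the cylinder wall whose angular half-width
## shrinks as beta*pi/N*(1 - z^2/z0^2); trapping segments fill the rest of the
## wall; convex end caps on the surface 2z^2 - rho^2 = 2z0^2 - R^2.
.trap_paracell <- function(params) {
  p <- .resolve(list(R = 0.0127, z0 = 2 * 0.0127, N = 8, beta = 0.9,
                     v_trap = 3.06), params)
  if (p$N < 2 || p$N != round(p$N)) stop("paracell electrode count N must be an integer >= 2")
  if (p$beta <= 0 || p$beta >= 1) stop("paracell beta must be in (0, 1)")
  R <- p$R; z0 <- p$z0; N <- p$N; beta <- p$beta; phi0 <- p$v_trap
  in_leaf <- function(x, y, z) {
    th <- atan2(y, x) %% (2 * pi / N)
    hw <- pmax(beta * pi / N * (1 - z^2 / z0^2), 0)
    dth <- pmin(th, 2 * pi / N - th)  # angular distance to nearest leaf centre
    dth <= hw
  }
  endcap <- function(x, y, z) 2 * z^2 - (x^2 + y^2) >= 2 * z0^2 - R^2
  wall <- function(x, y, z) (x^2 + y^2 >= R^2) & !endcap(x, y, z)
  el <- list(
    electrode_spec("end caps (convex)", "trapping", phi0, endcap),
    electrode_spec("trapping wall segments", "trapping", phi0,
                   function(x, y, z) wall(x, y, z) & !in_leaf(x, y, z)),
    electrode_spec("grounded leaves (excitation/detection)", "ground", 0,
                   function(x, y, z) wall(x, y, z) & in_leaf(x, y, z))
  )
  z_ext <- sqrt(z0^2 - R^2 / 2 + (1.002 * R)^2 / 2)  # just past wall/end-cap seam
  list(params = p, electrodes = el, R = R, z0 = z0, rho0 = R,
       symmetry = "N_fold",
       extent = list(x = R, y = R, z = z_ext), closed = TRUE)
}

## ---- voltage manipulation ----------------------------------------------

#' Scale or replace electrode voltages
#'
#' `set_trap_voltages()` assigns voltages by electrode role (used e.g. for
#' unit-voltage basis solutions); `scale_trap_voltages()` multiplies every
#' electrode voltage by a factor (electrostatic linearity makes this exact).
#'
#' @param trap A `trap_geometry`.
#' @param by_role Named list/vector, e.g. `list(trapping = 1, compensation = 0)`.
#'   Roles not named keep their voltage.
#' @return The modified `trap_geometry`.
#' @export
set_trap_voltages <- function(trap, by_role) {
  stopifnot(inherits(trap, "trap_geometry"))
  bad <- setdiff(names(by_role), .electrode_roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  trap$electrodes <- lapply(trap$electrodes, function(e) {
    if (e$role %in% names(by_role)) e$voltage <- as.numeric(by_role[[e$role]])
    e
  })
  trap
}

#' @rdname set_trap_voltages
#' @param factor Multiplier applied to every electrode voltage.
#' @export
scale_trap_voltages <- function(trap, factor) {
  stopifnot(inherits(trap, "trap_geometry"), is.finite(factor))
  trap$electrodes <- lapply(trap$electrodes, function(e) {
    e$voltage <- e$voltage * factor
    e
  })
  for (nm in intersect(names(trap$params), c("v_trap", "v_c"))) {
    trap$params[[nm]] <- trap$params[[nm]] * factor
  }
  trap
}

## ---- serialization ------------------------------------------------------

#' Serialize / restore a trap geometry as JSON
#'
#' The JSON records the design identifier, the fully resolved numeric
#' parameters and the electrode list (label, role, voltage). Reloading
#' rebuilds the geometry through [make_trap()], so defaults round-trip
#' bit-exactly.
#'
#' @param trap A `trap_geometry`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
trap_to_json <- function(trap, path = NULL) {
  stopifnot(inherits(trap, "trap_geometry"))
  obj <- list(
    kind = trap$kind,
    params = trap$params,
    electrodes = lapply(trap$electrodes, function(e) {
      list(label = e$label, role = e$role, voltage = e$voltage)
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname trap_to_json
#' @param json JSON string or path to a JSON file produced by [trap_to_json()].
#' @export
trap_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  ## JSON has no integer/double distinction; all parameters are lengths,
  ## counts or voltages stored as doubles
  params <- lapply(as.list(obj$params),
                   function(x) if (is.integer(x)) as.double(x) else x)
  params <- params[!vapply(params, is.null, TRUE)]  # nulls fall back to defaults
  ## vectors (e.g. ring voltages) survive as-is; scalars as length-1
  tr <- make_trap(obj$kind, as.list(params))
  ## restore any voltage edits recorded in the electrode list
  stored <- obj$electrodes
  if (!is.null(stored) && length(stored$voltage) == length(tr$electrodes)) {
    for (i in seq_along(tr$electrodes)) {
      tr$electrodes[[i]]$voltage <- stored$voltage[i]
    }
  }
  tr
}
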