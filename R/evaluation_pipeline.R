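#' Default evaluation configuration
#'
#' Grid, fit, cloud and truncation settings used by [evaluate_trap()].
#' Axisymmetric solves use a 257 x 513 grid over the (boxed) electrode
#' extent; 3-D solves use 129 nodes across each transverse extent.
#'
#' @return Nested list of options.
#' @export
default_config <- function() {
  list(
    trap_params = list(),
    grid = list(n_rho = 257L, n_z = 513L, n3 = 129L,
                tol = 1e-8, max_iter = 60000L, omega = 1.9,
                spacing = NULL, box_factor = 1.5),
    fit = list(rho_max = 0.010, z_max = 0.010, n_rho = 41L, n_z = 81L),
    cloud = list(m_over_z = 500, charge_number = 1L, B = 7,
                 r_cloud = 0.002, r_excitation = 0.006, z_cloud = 0.008),
    trunc = list(max_terms = 500L, tol = 1e-12),
    n_angles = 256L,
    verbose = FALSE
  )
}

.merge_config <- function(config) {
  utils::modifyList(default_config(), config)
}

#' Read an evaluation configuration from a YAML file
#'
#' The file may contain any subset of the sections of [default_config()]
#' (`trap_params`, `grid`, `fit`, `cloud`, `trunc`, `n_angles`).
#'
#' @param path YAML file path.
#' @return Full configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  .merge_config(yaml::read_yaml(path))
}

.has_analytic <- function(kind) kind %in% c("cubic", "cuboid", "cylindrical", "paracell")

## Default field source per design: closed forms where they are exact and
## fast; the numeric solver elsewhere. The paracell defaults to the numeric
## source: its exact azimuthally averaged field is purely quadratic, so the
## residual anharmonicity (and hence a finite comet time) only exists at
## finite grid resolution; see the methods vignette.
.default_source <- function(kind) {
  if (kind %in% c("cubic", "cuboid", "cylindrical")) "analytic" else "numeric"
}

## Term-wise azimuthal average of the rectangular-box series: the theta
## quadrature factorizes from the axial profile, which makes the average
## cheap on a (rho, z) lattice.
.avg_box <- function(rho_axis, z_axis, a, b, cc, vt, n_angles = 128L,
                     trunc = series_truncation()) {
  th <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  ct <- cos(th); st <- sin(th)
  nr <- length(rho_axis); nz <- length(z_axis)
  acc <- matrix(0, nr, nz)
  gap <- cc / 2 - max(abs(z_axis))
  xm <- outer(rho_axis, ct); ym <- outer(rho_axis, st)
  for (m in 0:(trunc$max_terms - 1)) {
    lam <- (2 * m + 1) * pi / a
    nu0 <- sqrt(lam^2 + (pi / b)^2)
    if (16 / pi^2 / (2 * m + 1) * exp(-nu0 * gap) < trunc$tol) break
    for (n in 0:(trunc$max_terms - 1)) {
      mu <- (2 * n + 1) * pi / b
      nu <- sqrt(lam^2 + mu^2)
      coef <- 16 / pi^2 * (-1)^(m + n) / ((2 * m + 1) * (2 * n + 1))
      if (abs(coef) * exp(-nu * gap) < trunc$tol) break
      ang <- rowMeans(cos(lam * xm) * cos(mu * ym))
      prof <- (exp(nu * (z_axis - cc / 2)) + exp(-nu * (z_axis + cc / 2))) /
        (1 + exp(-nu * cc))
      acc <- acc + coef * outer(ang, prof)
    }
  }
  vt * acc
}

## Azimuthal average of an analytic 3-D potential function by quadrature.
.avg_fun <- function(f, rho_axis, z_axis, n_angles = 256L) {
  th <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  ct <- cos(th); st <- sin(th)
  nr <- length(rho_axis); nz <- length(z_axis)
  out <- matrix(0, nr, nz)
  for (i in seq_len(nr)) {
    xs <- rep(rho_axis[i] * ct, times = nz)
    ys <- rep(rho_axis[i] * st, times = nz)
    zs <- rep(z_axis, each = n_angles)
    vals <- matrix(f(xs, ys, zs), n_angles, nz)
    out[i, ] <- colMeans(vals)
  }
  out
}

.analytic_average <- function(trap, cfg) {
  fit_ax <- .default_fit_axes(cfg$fit$rho_max, cfg$fit$z_max,
                              cfg$fit$n_rho, cfg$fit$n_z)
  trunc <- series_truncation(cfg$trunc$max_terms, cfg$trunc$tol)
  p <- trap$params
  phi_bar <- switch(trap$kind,
    cylindrical = outer(fit_ax$rho, fit_ax$z, function(r, z) {
      .pot_cylindrical(r, z, p$R, p$z0, p$v_trap, trunc)
    }),
    cubic = .avg_box(fit_ax$rho, fit_ax$z, p$a, p$a, p$a, p$v_trap,
                     trunc = trunc),
    cuboid = .avg_box(fit_ax$rho, fit_ax$z, p$a, p$b, p$c, p$v_trap,
                      trunc = trunc),
    paracell = .avg_fun(function(x, y, z) {
      .pot_paracell_full(x, y, z, p$R, p$z0, p$N, p$beta, p$v_trap)
    }, fit_ax$rho, fit_ax$z, cfg$n_angles),
    stop("no closed-form potential for kind '", trap$kind, "'")
  )
  avg <- averaged_potential(fit_ax$rho, fit_ax$z, phi_bar, source = "analytic")
  attr(avg, "solver_meta") <- list(source = "analytic", spacing = NA_real_,
                                   residual = NA_real_)
  avg
}

.auto_spacing <- function(trap, cfg) {
  g <- cfg$grid
  if (!is.null(g$spacing)) return(g$spacing)
  if (identical(trap$symmetry, "axisymmetric")) {
    fac <- if (trap$closed) 1 else g$box_factor
    c(fac * trap$extent$rho / (g$n_rho - 1L),
      fac * trap$extent$z / ((g$n_z - 1L) / 2))
  } else {
    c(trap$extent$x / ((g$n3 - 1L) / 2),
      trap$extent$y / ((g$n3 - 1L) / 2),
      trap$extent$z / ((g$n3 - 1L) / 2))
  }
}

.numeric_average <- function(trap, cfg) {
  g <- cfg$grid
  spacing <- .auto_spacing(trap, cfg)
  t0 <- proc.time()[["elapsed"]]
  bg <- rasterize(trap, spacing, box_factor = g$box_factor)
  pg <- solve_laplace(bg, tol = g$tol, max_iter = g$max_iter, omega = g$omega)
  if (isTRUE(cfg$verbose)) {
    message(sprintf("[%s] solve: %s nodes, %d sweeps, residual %.2e V (%.1f s)",
                    trap$kind, paste(dim(bg$mask), collapse = "x"),
                    pg$iterations, pg$residual,
                    proc.time()[["elapsed"]] - t0))
  }
  if (pg$type == "axisymmetric") {
    avg <- as_averaged_potential(pg)
  } else {
    fit_ax <- .default_fit_axes(cfg$fit$rho_max, cfg$fit$z_max,
                                cfg$fit$n_rho, cfg$fit$n_z)
    avg <- azimuthal_average(pg, n_angles = cfg$n_angles,
                             rho_axis = fit_ax$rho, z_axis = fit_ax$z)
  }
  attr(avg, "solver_meta") <- list(source = "numeric",
                                   spacing = max(spacing),
                                   residual = pg$residual)
  avg
}

.evaluate_one <- function(trap, cfg, source) {
  avg <- if (source == "analytic") .analytic_average(trap, cfg)
         else .numeric_average(trap, cfg)
  fit <- fit_harmonics(avg, d = trap$d,
                       rho_max = cfg$fit$rho_max, z_max = cfg$fit$z_max)
  cloud <- do.call(ion_cloud_spec, cfg$cloud)
  tc <- comet_time(fit, cloud)
  meta <- attr(avg, "solver_meta")
  data.frame(
    kind = trap$kind, source = source,
    A20n = fit$A20n, A40n = fit$A40n, A60n = fit$A60n,
    comet_time_s = tc, d_m = trap$d,
    C_V = fit$C, A20_Vm2 = fit$A20, A40_Vm4 = fit$A40, A60_Vm6 = fit$A60,
    rms_residual_V = fit$rms_residual, n_fit_points = fit$n_points,
    spacing_m = meta$spacing, solver_residual_V = meta$residual,
    reference = trap$kind != "ring_electrode",
    stringsAsFactors = FALSE
  )
}

#' Evaluate one cell design end to end
#'
#' Runs the full pipeline for a single trap: geometry construction, field
#' computation (closed-form series where exact, otherwise the finite
#' difference Laplace solver), azimuthal averaging, least-squares harmonic
#' fit over the 10 mm flight region, and the comet-formation time for the
#' default ion cloud. The pipeline is deterministic: rerunning with the same
#' configuration reproduces the row bit-exactly.
#'
#' @param kind A design identifier from [trap_kinds()], or a ready
#'   `trap_geometry`.
#' @param config Options (any subset of [default_config()]).
#' @param source `"auto"` (default per design), `"analytic"`, `"numeric"`,
#'   or `"both"` (two rows, for cross-checking).
#' @return A one-row data.frame (two rows for `"both"`): the machine-readable
#'   evaluation record.
#' @export
#' @examples
#' \donttest{
#' evaluate_trap("cubic")[, c("A20n", "A40n", "A60n", "comet_time_s")]
#' }
evaluate_trap <- function(kind, config = list(), source = c("auto", "analytic",
                                                            "numeric", "both")) {
  source <- match.arg(source)
  cfg <- .merge_config(config)
  trap <- if (inherits(kind, "trap_geometry")) kind
          else make_trap(kind, cfg$trap_params)
  if (source == "auto") source <- .default_source(trap$kind)
  if (source == "both") {
    if (!.has_analytic(trap$kind)) {
      stop("no closed-form potential for kind '", trap$kind,
           "'; cross-check mode needs one")
    }
    return(rbind(.evaluate_one(trap, cfg, "analytic"),
                 .evaluate_one(trap, cfg, "numeric")))
  }
  if (source == "analytic" && !.has_analytic(trap$kind)) {
    stop("no closed-form potential for kind '", trap$kind, "'")
  }
  .evaluate_one(trap, cfg, source)
}

#' Evaluate a set of cell designs
#'
#' Runs [evaluate_trap()] for each design and binds the rows. By default the
#' ten designs with reference tabulated coefficients are evaluated (the
#' trapping-ring-electrode cell is excluded; when requested explicitly its
#' row is flagged `reference = FALSE`). Per-trap failures are reported as
#' warnings without aborting the batch.
#'
#' @param kinds Character vector of design identifiers.
#' @param config See [evaluate_trap()].
#' @param source See [evaluate_trap()].
#' @return data.frame with one row per design (schema version in
#'   `attr(, "schema_version")`).
#' @export
evaluate_all <- function(kinds = setdiff(trap_kinds(), "ring_electrode"),
                         config = list(), source = "auto") {
  rows <- lapply(kinds, function(k) {
    tryCatch(evaluate_trap(k, config = config, source = source),
             error = function(e) {
               warning("evaluation of '", k, "' failed: ", conditionMessage(e),
                       call. = FALSE)
               out <- data.frame(kind = k, source = NA_character_,
                                 A20n = NA_real_, A40n = NA_real_,
                                 A60n = NA_real_, comet_time_s = NA_real_,
                                 d_m = NA_real_, C_V = NA_real_,
                                 A20_Vm2 = NA_real_, A40_Vm4 = NA_real_,
                                 A60_Vm6 = NA_real_, rms_residual_V = NA_real_,
                                 n_fit_points = NA_integer_,
                                 spacing_m = NA_real_,
                                 solver_residual_V = NA_real_,
                                 reference = k != "ring_electrode",
                                 stringsAsFactors = FALSE)
               out
             })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "schema_version") <- "1.0"
  out
}

#' Write an evaluation report
#'
#' @param rows data.frame from [evaluate_all()] / [evaluate_trap()].
#' @param csv,json Optional output paths; the CSV column order is fixed by
#'   the report schema.
#' @export
write_report <- function(rows, csv = NULL, json = NULL) {
  cols <- c("kind", "source", "A20n", "A40n", "A60n", "comet_time_s", "d_m",
            "C_V", "A20_Vm2", "A40_Vm4", "A60_Vm6", "rms_residual_V",
            "n_fit_points", "spacing_m", "solver_residual_V", "reference")
  rows <- rows[, cols]
  if (!is.null(csv)) utils::write.csv(rows, csv, row.names = FALSE)
  if (!is.null(json)) {
    obj <- list(schema_version = "1.0", rows = rows)
    jsonlite::write_json(obj, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(rows)
}
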